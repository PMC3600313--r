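{
  "name": "french_canadian",
  "sex": "female",
  "variant": "table",
  "pairs": [
    [28, 5.07636],
    [29, 5.26752],
    [30, 5.44571],
    [31, 5.6114],
    [32, 5.76505],
    [33, 5.90713],
    [34, 6.0381],
    [35, 6.15843],
    [36, 6.2686],
    [37, 6.36906],
    [38, 6.46028],
    [39, 6.54274],
    [40, 6.61689],
    [41, 6.6832],
    [42, 6.74215],
    [43, 6.79419],
    [44, 6.8398],
    [45, 6.87944],
    [46, 6.91358],
    [47, 6.94268],
    [48, 6.96722],
    [49, 6.98765],
    [50, 7.00445],
    [51, 7.01808],
    [52, 7.02902],
    [53, 7.03772],
    [54, 7.04465],
    [55, 7.05028],
    [56, 7.05508],
    [57, 7.05952],
    [58, 7.06406],
    [59, 7.06916],
    [60, 7.0753],
    [61, 7.08294],
    [62, 7.09255],
    [63, 7.1046],
    [64, 7.11955],
    [65, 7.13787],
    [66, 7.16002],
    [67, 7.18648],
    [68, 7.21771],
    [69, 7.25417],
    [70, 7.29634],
    [71, 7.34468],
    [72, 7.39966],
    [73, 7.46174],
    [74, 7.5314],
    [75, 7.60909],
    [76, 7.69529],
    [77, 7.79046],
    [78, 7.89507],
    [79, 8.00959],
    [80, 8.13448],
    [81, 8.2702],
    [82, 8.41724],
    [83, 8.57605],
    [84, 8.7471],
    [85, 8.93086],
    [86, 9.12779],
    [87, 9.33836],
    [88, 9.56305],
    [89, 9.8023],
    [90, 10.0566],
    [91, 10.32641],
    [92, 10.61219],
    [93, 10.91442],
    [94, 11.23356],
    [95, 11.57007],
    [96, 11.92443],
    [97, 12.29709],
    [98, 12.68854],
    [99, 13.09923],
    [100, 13.52963]
  ],
  "coverage": {
    "score": [28, 100],
    "age": [5.07636, 13.52963]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.83 yr); NOT the published french_canadian standard"
}
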