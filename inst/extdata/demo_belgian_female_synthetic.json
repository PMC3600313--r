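{
  "name": "belgian",
  "sex": "female",
  "variant": "table",
  "pairs": [
    [28, 6.64636],
    [29, 6.83752],
    [30, 7.01571],
    [31, 7.1814],
    [32, 7.33505],
    [33, 7.47713],
    [34, 7.6081],
    [35, 7.72843],
    [36, 7.8386],
    [37, 7.93906],
    [38, 8.03028],
    [39, 8.11274],
    [40, 8.18689],
    [41, 8.2532],
    [42, 8.31215],
    [43, 8.36419],
    [44, 8.4098],
    [45, 8.44944],
    [46, 8.48358],
    [47, 8.51268],
    [48, 8.53722],
    [49, 8.55765],
    [50, 8.57445],
    [51, 8.58808],
    [52, 8.59902],
    [53, 8.60772],
    [54, 8.61465],
    [55, 8.62028],
    [56, 8.62508],
    [57, 8.62952],
    [58, 8.63406],
    [59, 8.63916],
    [60, 8.6453],
    [61, 8.65294],
    [62, 8.66255],
    [63, 8.6746],
    [64, 8.68955],
    [65, 8.70787],
    [66, 8.73002],
    [67, 8.75648],
    [68, 8.78771],
    [69, 8.82417],
    [70, 8.86634],
    [71, 8.91468],
    [72, 8.96966],
    [73, 9.03174],
    [74, 9.1014],
    [75, 9.17909],
    [76, 9.26529],
    [77, 9.36046],
    [78, 9.46507],
    [79, 9.57959],
    [80, 9.70448],
    [81, 9.8402],
    [82, 9.98724],
    [83, 10.14605],
    [84, 10.3171],
    [85, 10.50086],
    [86, 10.69779],
    [87, 10.90836],
    [88, 11.13305],
    [89, 11.3723],
    [90, 11.6266],
    [91, 11.89641],
    [92, 12.18219],
    [93, 12.48442],
    [94, 12.80356],
    [95, 13.14007],
    [96, 13.49443],
    [97, 13.86709],
    [98, 14.25854],
    [99, 14.66923],
    [100, 15.09963]
  ],
  "coverage": {
    "score": [28, 100],
    "age": [6.64636, 15.09963]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +2.40 yr); NOT the published belgian standard"
}
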