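{
  "name": "french_canadian",
  "sex": "male",
  "variant": "table",
  "pairs": [
    [26, 5.09101],
    [27, 5.30039],
    [28, 5.4962],
    [29, 5.67891],
    [30, 5.84898],
    [31, 6.0069],
    [32, 6.15312],
    [33, 6.28813],
    [34, 6.41239],
    [35, 6.52637],
    [36, 6.63056],
    [37, 6.72541],
    [38, 6.81141],
    [39, 6.88902],
    [40, 6.95871],
    [41, 7.02096],
    [42, 7.07624],
    [43, 7.12502],
    [44, 7.16777],
    [45, 7.20497],
    [46, 7.23708],
    [47, 7.26458],
    [48, 7.28794],
    [49, 7.30762],
    [50, 7.32412],
    [51, 7.33788],
    [52, 7.34939],
    [53, 7.35912],
    [54, 7.36754],
    [55, 7.37513],
    [56, 7.38234],
    [57, 7.38966],
    [58, 7.39756],
    [59, 7.4065],
    [60, 7.41697],
    [61, 7.42943],
    [62, 7.44435],
    [63, 7.46221],
    [64, 7.48347],
    [65, 7.50862],
    [66, 7.53811],
    [67, 7.57243],
    [68, 7.61205],
    [69, 7.65743],
    [70, 7.70904],
    [71, 7.76737],
    [72, 7.83288],
    [73, 7.90604],
    [74, 7.98733],
    [75, 8.07722],
    [76, 8.17617],
    [77, 8.28466],
    [78, 8.40317],
    [79, 8.53216],
    [80, 8.67211],
    [81, 8.82348],
    [82, 8.98675],
    [83, 9.1624],
    [84, 9.35088],
    [85, 9.55269],
    [86, 9.76827],
    [87, 9.99812],
    [88, 10.2427],
    [89, 10.50248],
    [90, 10.77793],
    [91, 11.06952],
    [92, 11.37774],
    [93, 11.70304],
    [94, 12.04591],
    [95, 12.4068],
    [96, 12.7862],
    [97, 13.18458],
    [98, 13.6024]
  ],
  "coverage": {
    "score": [26, 98],
    "age": [5.09101, 13.6024]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.76 yr); NOT the published french_canadian standard"
}
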