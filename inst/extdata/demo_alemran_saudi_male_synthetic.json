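{
  "name": "alemran_saudi",
  "sex": "male",
  "variant": "table",
  "pairs": [
    [26, 4.73101],
    [27, 4.94039],
    [28, 5.1362],
    [29, 5.31891],
    [30, 5.48898],
    [31, 5.6469],
    [32, 5.79312],
    [33, 5.92813],
    [34, 6.05239],
    [35, 6.16637],
    [36, 6.27056],
    [37, 6.36541],
    [38, 6.45141],
    [39, 6.52902],
    [40, 6.59871],
    [41, 6.66096],
    [42, 6.71624],
    [43, 6.76502],
    [44, 6.80777],
    [45, 6.84497],
    [46, 6.87708],
    [47, 6.90458],
    [48, 6.92794],
    [49, 6.94762],
    [50, 6.96412],
    [51, 6.97788],
    [52, 6.98939],
    [53, 6.99912],
    [54, 7.00754],
    [55, 7.01513],
    [56, 7.02234],
    [57, 7.02966],
    [58, 7.03756],
    [59, 7.0465],
    [60, 7.05697],
    [61, 7.06943],
    [62, 7.08435],
    [63, 7.10221],
    [64, 7.12347],
    [65, 7.14862],
    [66, 7.17811],
    [67, 7.21243],
    [68, 7.25205],
    [69, 7.29743],
    [70, 7.34904],
    [71, 7.40737],
    [72, 7.47288],
    [73, 7.54604],
    [74, 7.62733],
    [75, 7.71722],
    [76, 7.81617],
    [77, 7.92466],
    [78, 8.04317],
    [79, 8.17216],
    [80, 8.31211],
    [81, 8.46348],
    [82, 8.62675],
    [83, 8.8024],
    [84, 8.99088],
    [85, 9.19269],
    [86, 9.40827],
    [87, 9.63812],
    [88, 9.8827],
    [89, 10.14248],
    [90, 10.41793],
    [91, 10.70952],
    [92, 11.01774],
    [93, 11.34304],
    [94, 11.68591],
    [95, 12.0468],
    [96, 12.4262],
    [97, 12.82458],
    [98, 13.2424]
  ],
  "coverage": {
    "age": [7.5, 17],
    "score": [26, 98]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.40 yr); NOT the published alemran_saudi standard"
}
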