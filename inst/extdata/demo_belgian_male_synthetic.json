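{
  "name": "belgian",
  "sex": "male",
  "variant": "table",
  "pairs": [
    [26, 6.45101],
    [27, 6.66039],
    [28, 6.8562],
    [29, 7.03891],
    [30, 7.20898],
    [31, 7.3669],
    [32, 7.51312],
    [33, 7.64813],
    [34, 7.77239],
    [35, 7.88637],
    [36, 7.99056],
    [37, 8.08541],
    [38, 8.17141],
    [39, 8.24902],
    [40, 8.31871],
    [41, 8.38096],
    [42, 8.43624],
    [43, 8.48502],
    [44, 8.52777],
    [45, 8.56497],
    [46, 8.59708],
    [47, 8.62458],
    [48, 8.64794],
    [49, 8.66762],
    [50, 8.68412],
    [51, 8.69788],
    [52, 8.70939],
    [53, 8.71912],
    [54, 8.72754],
    [55, 8.73513],
    [56, 8.74234],
    [57, 8.74966],
    [58, 8.75756],
    [59, 8.7665],
    [60, 8.77697],
    [61, 8.78943],
    [62, 8.80435],
    [63, 8.82221],
    [64, 8.84347],
    [65, 8.86862],
    [66, 8.89811],
    [67, 8.93243],
    [68, 8.97205],
    [69, 9.01743],
    [70, 9.06904],
    [71, 9.12737],
    [72, 9.19288],
    [73, 9.26604],
    [74, 9.34733],
    [75, 9.43722],
    [76, 9.53617],
    [77, 9.64466],
    [78, 9.76317],
    [79, 9.89216],
    [80, 10.03211],
    [81, 10.18348],
    [82, 10.34675],
    [83, 10.5224],
    [84, 10.71088],
    [85, 10.91269],
    [86, 11.12827],
    [87, 11.35812],
    [88, 11.6027],
    [89, 11.86248],
    [90, 12.13793],
    [91, 12.42952],
    [92, 12.73774],
    [93, 13.06304],
    [94, 13.40591],
    [95, 13.7668],
    [96, 14.1462],
    [97, 14.54458],
    [98, 14.9624]
  ],
  "coverage": {
    "score": [26, 98],
    "age": [6.45101, 14.9624]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +2.12 yr); NOT the published belgian standard"
}
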