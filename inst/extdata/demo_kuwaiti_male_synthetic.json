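{
  "name": "kuwaiti",
  "sex": "male",
  "variant": "table",
  "pairs": [
    [26, 4.63101],
    [27, 4.84039],
    [28, 5.0362],
    [29, 5.21891],
    [30, 5.38898],
    [31, 5.5469],
    [32, 5.69312],
    [33, 5.82813],
    [34, 5.95239],
    [35, 6.06637],
    [36, 6.17056],
    [37, 6.26541],
    [38, 6.35141],
    [39, 6.42902],
    [40, 6.49871],
    [41, 6.56096],
    [42, 6.61624],
    [43, 6.66502],
    [44, 6.70777],
    [45, 6.74497],
    [46, 6.77708],
    [47, 6.80458],
    [48, 6.82794],
    [49, 6.84762],
    [50, 6.86412],
    [51, 6.87788],
    [52, 6.88939],
    [53, 6.89912],
    [54, 6.90754],
    [55, 6.91513],
    [56, 6.92234],
    [57, 6.92966],
    [58, 6.93756],
    [59, 6.9465],
    [60, 6.95697],
    [61, 6.96943],
    [62, 6.98435],
    [63, 7.00221],
    [64, 7.02347],
    [65, 7.04862],
    [66, 7.07811],
    [67, 7.11243],
    [68, 7.15205],
    [69, 7.19743],
    [70, 7.24904],
    [71, 7.30737],
    [72, 7.37288],
    [73, 7.44604],
    [74, 7.52733],
    [75, 7.61722],
    [76, 7.71617],
    [77, 7.82466],
    [78, 7.94317],
    [79, 8.07216],
    [80, 8.21211],
    [81, 8.36348],
    [82, 8.52675],
    [83, 8.7024],
    [84, 8.89088],
    [85, 9.09269],
    [86, 9.30827],
    [87, 9.53812],
    [88, 9.7827],
    [89, 10.04248],
    [90, 10.31793],
    [91, 10.60952],
    [92, 10.91774],
    [93, 11.24304],
    [94, 11.58591],
    [95, 11.9468],
    [96, 12.3262],
    [97, 12.72458],
    [98, 13.1424]
  ],
  "coverage": {
    "score": [26, 98],
    "age": [4.63101, 13.1424]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.30 yr); NOT the published kuwaiti standard"
}
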