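{
  "name": "alemran_saudi",
  "sex": "female",
  "variant": "table",
  "pairs": [
    [28, 5.08636],
    [29, 5.27752],
    [30, 5.45571],
    [31, 5.6214],
    [32, 5.77505],
    [33, 5.91713],
    [34, 6.0481],
    [35, 6.16843],
    [36, 6.2786],
    [37, 6.37906],
    [38, 6.47028],
    [39, 6.55274],
    [40, 6.62689],
    [41, 6.6932],
    [42, 6.75215],
    [43, 6.80419],
    [44, 6.8498],
    [45, 6.88944],
    [46, 6.92358],
    [47, 6.95268],
    [48, 6.97722],
    [49, 6.99765],
    [50, 7.01445],
    [51, 7.02808],
    [52, 7.03902],
    [53, 7.04772],
    [54, 7.05465],
    [55, 7.06028],
    [56, 7.06508],
    [57, 7.06952],
    [58, 7.07406],
    [59, 7.07916],
    [60, 7.0853],
    [61, 7.09294],
    [62, 7.10255],
    [63, 7.1146],
    [64, 7.12955],
    [65, 7.14787],
    [66, 7.17002],
    [67, 7.19648],
    [68, 7.22771],
    [69, 7.26417],
    [70, 7.30634],
    [71, 7.35468],
    [72, 7.40966],
    [73, 7.47174],
    [74, 7.5414],
    [75, 7.61909],
    [76, 7.70529],
    [77, 7.80046],
    [78, 7.90507],
    [79, 8.01959],
    [80, 8.14448],
    [81, 8.2802],
    [82, 8.42724],
    [83, 8.58605],
    [84, 8.7571],
    [85, 8.94086],
    [86, 9.13779],
    [87, 9.34836],
    [88, 9.57305],
    [89, 9.8123],
    [90, 10.0666],
    [91, 10.33641],
    [92, 10.62219],
    [93, 10.92442],
    [94, 11.24356],
    [95, 11.58007],
    [96, 11.93443],
    [97, 12.30709],
    [98, 12.69854],
    [99, 13.10923],
    [100, 13.53963]
  ],
  "coverage": {
    "age": [7.5, 17],
    "score": [28, 100]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.84 yr); NOT the published alemran_saudi standard"
}
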