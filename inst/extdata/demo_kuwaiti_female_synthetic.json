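{
  "name": "kuwaiti",
  "sex": "female",
  "variant": "table",
  "pairs": [
    [28, 4.98636],
    [29, 5.17752],
    [30, 5.35571],
    [31, 5.5214],
    [32, 5.67505],
    [33, 5.81713],
    [34, 5.9481],
    [35, 6.06843],
    [36, 6.1786],
    [37, 6.27906],
    [38, 6.37028],
    [39, 6.45274],
    [40, 6.52689],
    [41, 6.5932],
    [42, 6.65215],
    [43, 6.70419],
    [44, 6.7498],
    [45, 6.78944],
    [46, 6.82358],
    [47, 6.85268],
    [48, 6.87722],
    [49, 6.89765],
    [50, 6.91445],
    [51, 6.92808],
    [52, 6.93902],
    [53, 6.94772],
    [54, 6.95465],
    [55, 6.96028],
    [56, 6.96508],
    [57, 6.96952],
    [58, 6.97406],
    [59, 6.97916],
    [60, 6.9853],
    [61, 6.99294],
    [62, 7.00255],
    [63, 7.0146],
    [64, 7.02955],
    [65, 7.04787],
    [66, 7.07002],
    [67, 7.09648],
    [68, 7.12771],
    [69, 7.16417],
    [70, 7.20634],
    [71, 7.25468],
    [72, 7.30966],
    [73, 7.37174],
    [74, 7.4414],
    [75, 7.51909],
    [76, 7.60529],
    [77, 7.70046],
    [78, 7.80507],
    [79, 7.91959],
    [80, 8.04448],
    [81, 8.1802],
    [82, 8.32724],
    [83, 8.48605],
    [84, 8.6571],
    [85, 8.84086],
    [86, 9.03779],
    [87, 9.24836],
    [88, 9.47305],
    [89, 9.7123],
    [90, 9.9666],
    [91, 10.23641],
    [92, 10.52219],
    [93, 10.82442],
    [94, 11.14356],
    [95, 11.48007],
    [96, 11.83443],
    [97, 12.20709],
    [98, 12.59854],
    [99, 13.00923],
    [100, 13.43963]
  ],
  "coverage": {
    "score": [28, 100],
    "age": [4.98636, 13.43963]
  },
  "provenance": "SYNTHETIC demo standard (refit Saudi cubic shifted +0.74 yr); NOT the published kuwaiti standard"
}
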