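{
  "name": "saudi",
  "sex": "male",
  "variant": "cubic",
  "coefficients": {
    "b0": -7.42382685543318,
    "b1": 0.741038514310028,
    "b2": -0.0131570115779566,
    "b3": 7.86283705478422e-05
  },
  "score_range": [25.8, 98.8],
  "coverage": {
    "score": [25.8, 98.8],
    "age": [4.28745889215836, 13.1909800552416]
  },
  "provenance": "least-squares cubic refit of the published Saudi prediction table",
  "metadata": {
    "fit": {
      "rmse": 2.83482840067464e-06,
      "r_squared": 0.999999999998292,
      "n": 63
    },
    "published_coefficients": {
      "b0": -7.424,
      "b1": 0.741,
      "b2": -0.013,
      "b3": 7.863e-05
    }
  }
}
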