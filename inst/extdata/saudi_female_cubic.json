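{
  "name": "saudi",
  "sex": "female",
  "variant": "cubic",
  "coefficients": {
    "b0": -8.26851965460241,
    "b1": 0.757122372108154,
    "b2": -0.0132561094914186,
    "b3": 7.78170035903498e-05
  },
  "score_range": [27.2, 100],
  "coverage": {
    "score": [27.2, 100],
    "age": [4.08377080927514, 12.6996262323763]
  },
  "provenance": "least-squares cubic refit of the published Saudi prediction table",
  "metadata": {
    "fit": {
      "rmse": 2.98427892293769e-06,
      "r_squared": 0.999999999998182,
      "n": 63
    },
    "published_coefficients": {
      "b0": -8.269,
      "b1": 0.757,
      "b2": -0.013,
      "b3": 7.782e-05
    }
  }
}
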