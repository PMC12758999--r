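[
  {
    "organ": "heart",
    "a": 3,
    "d50_gy": 18.788535332,
    "gamma50": 1.318479516,
    "endpoint": "late cardiac mortality",
    "source": "fitted: two-point inversion of reported (EUD, NTCP) pairs (16 Gy, 30%) and (6.6 Gy, 0.4%)"
  },
  {
    "organ": "thyroid",
    "a": 1,
    "d50_gy": 53.804556461,
    "gamma50": 0.726290171,
    "endpoint": "radiation-induced thyroid dysfunction",
    "source": "fitted: two-point inversion of reported (EUD, NTCP) pairs (27.1 Gy, 12%) and (8.7 Gy, 0.5%)"
  },
  {
    "organ": "lungs",
    "a": 1,
    "d50_gy": 24.5,
    "gamma50": 2,
    "endpoint": "pneumonitis",
    "source": "illustrative"
  },
  {
    "organ": "kidneys",
    "a": 1,
    "d50_gy": 28,
    "gamma50": 2.5,
    "endpoint": "clinical nephritis",
    "source": "illustrative"
  },
  {
    "organ": "spinal_cord",
    "a": 13,
    "d50_gy": 66.5,
    "gamma50": 4,
    "endpoint": "myelitis",
    "source": "illustrative"
  },
  {
    "organ": "brain",
    "a": 5,
    "d50_gy": 60,
    "gamma50": 3,
    "endpoint": "necrosis",
    "source": "illustrative"
  }
]
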