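{
  "species": ["S", "E", "Ea", "Sub", "pSub", "Pase1", "CE", "CEa", "Prom", "PromA", "P2"],
  "sub_mass": {
    "Sub": 1,
    "pSub": 1,
    "CE": 1,
    "CEa": 1,
    "PromA": 1
  },
  "reactions": [
    {
      "name": "activation",
      "reactants": {
        "S": 1,
        "E": 1
      },
      "products": {
        "S": 1,
        "Ea": 1
      },
      "rate": 0.0002
    },
    {
      "name": "deactivation",
      "reactants": {
        "Ea": 1
      },
      "products": {
        "E": 1
      },
      "rate": 0.01
    },
    {
      "name": "phospho_active",
      "reactants": {
        "Ea": 1,
        "Sub": 1
      },
      "products": {
        "Ea": 1,
        "pSub": 1
      },
      "rate": 0.000175
    },
    {
      "name": "phospho_leak",
      "reactants": {
        "E": 1,
        "Sub": 1
      },
      "products": {
        "E": 1,
        "pSub": 1
      },
      "rate": 1.75e-05
    },
    {
      "name": "dephospho_p1",
      "reactants": {
        "pSub": 1,
        "Pase1": 1
      },
      "products": {
        "Sub": 1,
        "Pase1": 1
      },
      "rate": 4e-05
    },
    {
      "name": "fb_bind_E",
      "reactants": {
        "E": 1,
        "pSub": 1
      },
      "products": {
        "CE": 1
      },
      "rate": 0.0249
    },
    {
      "name": "fb_unbind_E",
      "reactants": {
        "CE": 1
      },
      "products": {
        "E": 1,
        "pSub": 1
      },
      "rate": 0.1
    },
    {
      "name": "fb_bind_Ea",
      "reactants": {
        "Ea": 1,
        "pSub": 1
      },
      "products": {
        "CEa": 1
      },
      "rate": 0.0249
    },
    {
      "name": "fb_unbind_Ea",
      "reactants": {
        "CEa": 1
      },
      "products": {
        "Ea": 1,
        "pSub": 1
      },
      "rate": 0.1
    },
    {
      "name": "prom_bind",
      "reactants": {
        "pSub": 1,
        "Prom": 1
      },
      "products": {
        "PromA": 1
      },
      "rate": 2e-07
    },
    {
      "name": "prom_unbind",
      "reactants": {
        "PromA": 1
      },
      "products": {
        "pSub": 1,
        "Prom": 1
      },
      "rate": 6e-05
    },
    {
      "name": "pase2_prod",
      "reactants": {
        "PromA": 1
      },
      "products": {
        "PromA": 1,
        "P2": 1
      },
      "rate": 0.001
    },
    {
      "name": "pase2_decay",
      "reactants": {
        "P2": 1
      },
      "products": {},
      "rate": 0.0002
    },
    {
      "name": "dephospho_p2",
      "reactants": {
        "pSub": 1,
        "P2": 1
      },
      "products": {
        "Sub": 1,
        "P2": 1
      },
      "rate": 1e-05
    }
  ]
}
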