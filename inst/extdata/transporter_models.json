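{
  "_meta": "oometab transporter fixtures v1.  Km/Vmax are synthetic fixture constants chosen to reproduce the qualitative substrate profiles of the corresponding transporter families; only ordinal relations are meaningful.",
  "models": [
    {
      "name": "SNAT2-like",
      "mechanism": "symport",
      "stoichiometry": "Na+-coupled (metadata only)",
      "exchange_rate_per_h": 0,
      "substrates": [
        {
          "substrate": "Alanine",
          "Km": 300,
          "Vmax": 769
        },
        {
          "substrate": "Serine",
          "Km": 400,
          "Vmax": 2050
        },
        {
          "substrate": "Glycine",
          "Km": 500,
          "Vmax": 1566
        },
        {
          "substrate": "Proline",
          "Km": 150,
          "Vmax": 2818
        },
        {
          "substrate": "Methionine",
          "Km": 300,
          "Vmax": 3382
        },
        {
          "substrate": "Asparagine",
          "Km": 150,
          "Vmax": 1879
        },
        {
          "substrate": "Glutamine",
          "Km": 400,
          "Vmax": 1074
        },
        {
          "substrate": "Leucine",
          "Km": 600,
          "Vmax": 3560
        }
      ]
    },
    {
      "name": "SNAT1-like",
      "mechanism": "symport",
      "stoichiometry": "Na+-coupled (metadata only)",
      "exchange_rate_per_h": 0,
      "substrates": [
        {
          "substrate": "Alanine",
          "Km": 300,
          "Vmax": 671
        },
        {
          "substrate": "Serine",
          "Km": 400,
          "Vmax": 1789
        },
        {
          "substrate": "Glycine",
          "Km": 500,
          "Vmax": 1367
        },
        {
          "substrate": "Methionine",
          "Km": 300,
          "Vmax": 2952
        },
        {
          "substrate": "Asparagine",
          "Km": 150,
          "Vmax": 1640
        },
        {
          "substrate": "Glutamine",
          "Km": 400,
          "Vmax": 937
        }
      ]
    },
    {
      "name": "B0AT1-like",
      "mechanism": "symport",
      "stoichiometry": "Na+-coupled (metadata only)",
      "exchange_rate_per_h": 0,
      "substrates": [
        {
          "substrate": "Alanine",
          "Km": 600,
          "Vmax": 1953
        },
        {
          "substrate": "Serine",
          "Km": 500,
          "Vmax": 3255
        },
        {
          "substrate": "Glycine",
          "Km": 700,
          "Vmax": 2785
        },
        {
          "substrate": "Proline",
          "Km": 400,
          "Vmax": 9548
        },
        {
          "substrate": "Methionine",
          "Km": 300,
          "Vmax": 4297
        },
        {
          "substrate": "Asparagine",
          "Km": 300,
          "Vmax": 4774
        },
        {
          "substrate": "Glutamine",
          "Km": 500,
          "Vmax": 1705
        },
        {
          "substrate": "Leucine",
          "Km": 300,
          "Vmax": 2261
        },
        {
          "substrate": "Isoleucine",
          "Km": 300,
          "Vmax": 2261
        },
        {
          "substrate": "Valine",
          "Km": 300,
          "Vmax": 3069
        },
        {
          "substrate": "Phenylalanine",
          "Km": 300,
          "Vmax": 3580
        },
        {
          "substrate": "Tyrosine",
          "Km": 250,
          "Vmax": 7161
        },
        {
          "substrate": "Histidine",
          "Km": 500,
          "Vmax": 3580
        },
        {
          "substrate": "Threonine",
          "Km": 600,
          "Vmax": 2527
        },
        {
          "substrate": "Cysteine",
          "Km": 400,
          "Vmax": 4092
        }
      ]
    },
    {
      "name": "EAAT1-like",
      "mechanism": "symport",
      "stoichiometry": "Na+-coupled (metadata only)",
      "exchange_rate_per_h": 0,
      "substrates": [
        {
          "substrate": "Glutamic acid",
          "Km": 100,
          "Vmax": 400
        },
        {
          "substrate": "Aspartic acid",
          "Km": 100,
          "Vmax": 400
        }
      ]
    },
    {
      "name": "LAT1-like",
      "mechanism": "antiport",
      "stoichiometry": "1:1 amino acid exchange",
      "exchange_rate_per_h": 0.5,
      "substrates": [
        {
          "substrate": "Leucine",
          "Km": 200,
          "Vmax": 0
        },
        {
          "substrate": "Isoleucine",
          "Km": 150,
          "Vmax": 0
        },
        {
          "substrate": "Valine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Phenylalanine",
          "Km": 200,
          "Vmax": 0
        },
        {
          "substrate": "Tryptophan",
          "Km": 150,
          "Vmax": 0
        },
        {
          "substrate": "Tyrosine",
          "Km": 250,
          "Vmax": 0
        },
        {
          "substrate": "Histidine",
          "Km": 400,
          "Vmax": 0
        },
        {
          "substrate": "Methionine",
          "Km": 250,
          "Vmax": 0
        },
        {
          "substrate": "Glutamine",
          "Km": 600,
          "Vmax": 0
        }
      ]
    },
    {
      "name": "ASCT2-like",
      "mechanism": "antiport",
      "stoichiometry": "1:1 Na+-dependent exchange",
      "exchange_rate_per_h": 0.5,
      "substrates": [
        {
          "substrate": "Alanine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Serine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Threonine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Cysteine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Glutamine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Asparagine",
          "Km": 300,
          "Vmax": 0
        },
        {
          "substrate": "Methionine",
          "Km": 400,
          "Vmax": 0
        },
        {
          "substrate": "Glycine",
          "Km": 600,
          "Vmax": 0
        },
        {
          "substrate": "Glutamic acid",
          "Km": 2000,
          "Vmax": 0
        }
      ]
    },
    {
      "name": "Un-injected",
      "mechanism": "none",
      "stoichiometry": "",
      "exchange_rate_per_h": 0,
      "substrates": []
    }
  ]
}
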