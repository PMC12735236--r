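{
  "comment": "Diagnostic negative-mode fragmentation rules for isomalabaricane structural classes. Rule types: 'loss' (neutral-loss chain from [M-H]-), 'series' (nominal fragment m/z set with min_hits), 'parallel_series' (peak pairs separated by a fixed neutral offset), 'parity' (even nominal precursor mass / nitrogen rule). Weights of scoring rules sum to 1 per class; 'forbidden' rules zero the class when they fire.",
  "classes": [
    {
      "class_id": "SC_ACID",
      "description": "unsaturated side chain terminating in a free carboxyl group: CO2 loss then CO2+CH4 loss",
      "rules": [
        {"label": "[M-H-CO2]-", "type": "loss", "chain": ["CO2"], "required": true, "weight": 0.5},
        {"label": "[M-H-CO2-CH4]-", "type": "loss", "chain": ["CO2", "CH4"], "required": true, "weight": 0.5}
      ]
    },
    {
      "class_id": "SC_ACID_HYDROXY",
      "description": "side-chain acid plus hydroxyl: CO2, H2O and CO2+H2O losses, no CO2+CH4",
      "rules": [
        {"label": "[M-H-CO2]-", "type": "loss", "chain": ["CO2"], "required": true, "weight": 0.4},
        {"label": "[M-H-H2O]-", "type": "loss", "chain": ["H2O"], "required": true, "weight": 0.3},
        {"label": "[M-H-CO2-H2O]-", "type": "loss", "chain": ["CO2", "H2O"], "required": true, "weight": 0.3},
        {"label": "no [M-H-CO2-CH4]-", "type": "loss", "chain": ["CO2", "CH4"], "forbidden": true}
      ]
    },
    {
      "class_id": "CORE_3OH_4COOH",
      "description": "3-hydroxy-4-carboxy core (jaspiferal-type): spectrum dominated by CO2+H2O loss, CO2+CH4 absent",
      "rules": [
        {"label": "[M-H-CO2-H2O]- (base region)", "type": "loss", "chain": ["CO2", "H2O"], "required": true, "weight": 0.7, "max_intensity_rank": 3},
        {"label": "jaspiferal core series", "type": "series", "nominal_mzs": [269, 257, 215, 183], "min_hits": 3, "weight": 0.3},
        {"label": "no [M-H-CO2-CH4]-", "type": "loss", "chain": ["CO2", "CH4"], "forbidden": true}
      ]
    },
    {
      "class_id": "CARBONYL_CO",
      "description": "carbonyl-bearing: CO-loss series [M-H-CO]-, [M-H-CO2]-, [M-H-CO-CO2]-",
      "rules": [
        {"label": "[M-H-CO]-", "type": "loss", "chain": ["CO"], "required": true, "weight": 0.4},
        {"label": "[M-H-CO2]-", "type": "loss", "chain": ["CO2"], "required": true, "weight": 0.3},
        {"label": "[M-H-CO-CO2]-", "type": "loss", "chain": ["CO", "CO2"], "required": true, "weight": 0.3}
      ]
    },
    {
      "class_id": "ACETOXY_MOD",
      "description": "3-O-acetyl modification: acetic-acid loss and/or two parallel fragment series separated by 44 Da (C2H4O)",
      "rules": [
        {"label": "[M-H-C2H4O2]-", "type": "loss", "chain": ["C2H4O2"], "weight": 0.5},
        {"label": "parallel series offset C2H4O", "type": "parallel_series", "offset_formula": "C2H4O", "min_pairs": 3, "weight": 0.5}
      ]
    },
    {
      "class_id": "GLYCOSIDE",
      "description": "triterpene glycoside: sequential HexNAc then Hex Y-ion losses, deprotonated HexNAc at 202, hexose cross-ring ion at 262",
      "rules": [
        {"label": "Y1 [M-H-HexNAc]-", "type": "loss", "chain": ["C8H13NO5"], "weight": 0.3},
        {"label": "Y2 [M-H-HexNAc-Hex]-", "type": "loss", "chain": ["C8H13NO5", "C6H10O5"], "weight": 0.3},
        {"label": "HexNAc anion 202", "type": "series", "nominal_mzs": [202], "min_hits": 1, "weight": 0.2},
        {"label": "hexose cross-ring 262", "type": "series", "nominal_mzs": [262], "min_hits": 1, "weight": 0.2}
      ]
    },
    {
      "class_id": "NITROGENOUS",
      "description": "nitrogen-containing congener: even nominal precursor (anion nitrogen rule) and combined CO2 + C2H3NO losses",
      "rules": [
        {"label": "even nominal precursor", "type": "parity", "weight": 0.3},
        {"label": "[M-H-CO2-C2H3NO]-", "type": "loss", "chain": ["CO2", "C2H3NO"], "weight": 0.35},
        {"label": "[M-H-CO2-CH4-C2H3NO]-", "type": "loss", "chain": ["CO2", "CH4", "C2H3NO"], "weight": 0.35}
      ]
    },
    {
      "class_id": "LYSO_PI",
      "description": "lysophosphatidylinositol-type lipid: inositol-phosphate headgroup ions 259/241/223 plus hexose losses",
      "rules": [
        {"label": "headgroup 259/241/223", "type": "series", "nominal_mzs": [259, 241, 223], "min_hits": 2, "weight": 0.6},
        {"label": "[M-H-C6H10O5]-", "type": "loss", "chain": ["C6H10O5"], "weight": 0.2},
        {"label": "[M-H-C6H12O6]-", "type": "loss", "chain": ["C6H12O6"], "weight": 0.2}
      ]
    },
    {
      "class_id": "CORE_RAA",
      "description": "RAA-type core: side-chain cleavage series 301/285/261/245/229",
      "rules": [
        {"label": "RAA core series", "type": "series", "nominal_mzs": [301, 285, 261, 245, 229], "min_hits": 3, "weight": 1.0}
      ]
    },
    {
      "class_id": "CORE_JASPIFERAL",
      "description": "jaspiferal-type core series 269/257/215/183",
      "rules": [
        {"label": "jaspiferal core series", "type": "series", "nominal_mzs": [269, 257, 215, 183], "min_hits": 3, "weight": 1.0}
      ]
    },
    {
      "class_id": "CORE_OXY",
      "description": "extra-oxygenated core: fragment ions 247 [C16H23O2]- and 231 [C15H19O2]-",
      "rules": [
        {"label": "oxygenated core 247/231", "type": "series", "nominal_mzs": [247, 231], "min_hits": 2, "weight": 1.0}
      ]
    }
  ]
}
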