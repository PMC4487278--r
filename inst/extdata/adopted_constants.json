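{
  "version": "1.0",
  "corrections": {
    "lamperti": {
      "values": {
        "k_ion": 1,
        "k_humidity": 0.998,
        "k_att": 1.0087,
        "k_el": 1.0008,
        "k_sc": 0.9987,
        "k_fl": 0.9979,
        "k_br_over_1mg": 1,
        "k_ii": 1,
        "k_dia": 1
      },
      "uncertainties_pct": {
        "k_ion": 0.03,
        "k_humidity": 0.03,
        "k_att": 0.11,
        "k_el": 0.06,
        "k_sc": 0.03,
        "k_fl": 0.05,
        "k_br_over_1mg": 0.02,
        "k_ii": 0.2,
        "k_dia": 0.1
      }
    },
    "ritz": {
      "values": {
        "k_ion": 1,
        "k_humidity": 0.998,
        "k_att": 1.0283,
        "k_el": 1,
        "k_sc": 0.997,
        "k_fl": 0.9969,
        "k_br_over_1mg": 1,
        "k_ii": 1,
        "k_dia": 1
      },
      "uncertainties_pct": {
        "k_ion": 0.03,
        "k_humidity": 0.03,
        "k_att": 0.36,
        "k_el": 0.08,
        "k_sc": 0.03,
        "k_fl": 0.05,
        "k_br_over_1mg": 0.02,
        "k_ii": 0.2,
        "k_dia": 0.1
      }
    }
  },
  "alternatives": {
    "k_ii": {
      "value": 0.998,
      "u": 0.0004,
      "note": "Computed compromise from mean-energy analyses; the adopted policy value remains 1.0 with a 0.2 % standard uncertainty."
    }
  },
  "budget": {
    "type_A": {
      "v_eff": 0.04,
      "k_ion": 0.03,
      "polarity": 0.02
    },
    "type_B": {
      "lamperti": {
        "i_net": 0.06,
        "w_over_e": 0.15,
        "rho_0": 0.03,
        "v_eff": 0.01,
        "k_humidity": 0.03,
        "k_att": 0.11,
        "k_el": 0.06,
        "k_sc": 0.03,
        "k_fl": 0.05,
        "k_br_over_1mg": 0.02,
        "k_ii": 0.04,
        "k_dia": 0.1,
        "k_field_distortion": 0.2
      },
      "ritz": {
        "i_net": 0.06,
        "w_over_e": 0.15,
        "rho_0": 0.03,
        "v_eff": 0.01,
        "k_humidity": 0.03,
        "k_att": 0.36,
        "k_el": 0.08,
        "k_sc": 0.03,
        "k_fl": 0.05,
        "k_br_over_1mg": 0.02,
        "k_ii": 0.04,
        "k_dia": 0.1,
        "k_field_distortion": 0.2
      }
    }
  }
}
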