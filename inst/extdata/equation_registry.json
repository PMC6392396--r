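[
  {
    "eq_id": "cane1987_bee_dw_itd",
    "response": "dry_weight_mg",
    "predictor": "itd_mm",
    "alpha_ln": 0.6453451,
    "beta": 2.4691358,
    "sigma_resid_ln": null,
    "scope": {"taxon": ["Apoidea"]},
    "source": "Cane JH (1987) Estimation of bee size using intertegular span (Apoidea). J Kansas Entomol Soc 60:145-147. Published as ITD = 0.77 * W^0.405; inverted to canonical ln-scale form at transcription."
  },
  {
    "eq_id": "rogers1976_insect_dw_bl",
    "response": "dry_weight_mg",
    "predictor": "body_length_mm",
    "alpha_ln": -3.4900328,
    "beta": 2.62,
    "sigma_resid_ln": null,
    "scope": {"taxon": ["Diptera", "Hymenoptera", "Lepidoptera", "Coleoptera", "Hemiptera", "Orthoptera"]},
    "source": "Rogers LE, Hinds WT, Buschbom RL (1976) A general weight vs. length relationship for insects. Ann Entomol Soc Am 69:387-389. Published as W = 0.0305 * L^2.62 (mg, mm)."
  },
  {
    "eq_id": "synthetic_bee_foraging_itd",
    "response": "foraging_distance_km",
    "predictor": "itd_mm",
    "alpha_ln": -1.60,
    "beta": 2.40,
    "sigma_resid_ln": 0.50,
    "scope": {"taxon": ["Apoidea"]},
    "source": "Synthetic example equation illustrating the registry schema; replace with transcribed published coefficients before scientific use."
  },
  {
    "eq_id": "synthetic_apidae_tongue_itd",
    "response": "tongue_length_mm",
    "predictor": "itd_mm",
    "alpha_ln": 0.40,
    "beta": 0.96,
    "sigma_resid_ln": 0.18,
    "scope": {"taxon": ["Apidae"]},
    "source": "Synthetic example equation illustrating the registry schema; replace with transcribed published coefficients before scientific use."
  },
  {
    "eq_id": "synthetic_halictidae_tongue_itd",
    "response": "tongue_length_mm",
    "predictor": "itd_mm",
    "alpha_ln": 0.05,
    "beta": 1.02,
    "sigma_resid_ln": 0.20,
    "scope": {"taxon": ["Halictidae"]},
    "source": "Synthetic example equation illustrating the registry schema; replace with transcribed published coefficients before scientific use."
  },
  {
    "eq_id": "synthetic_bee_wing_loading_itd",
    "response": "wing_loading",
    "predictor": "itd_mm",
    "alpha_ln": -0.90,
    "beta": 1.10,
    "sigma_resid_ln": null,
    "scope": {"taxon": ["Apoidea"]},
    "source": "Synthetic example equation illustrating the registry schema; replace with transcribed published coefficients before scientific use."
  },
  {
    "eq_id": "synthetic_bee_nectar_load_itd",
    "response": "nectar_load_mg",
    "predictor": "itd_mm",
    "alpha_ln": 0.95,
    "beta": 2.20,
    "sigma_resid_ln": 0.60,
    "scope": {"taxon": ["Apoidea"]},
    "source": "Synthetic example equation illustrating the registry schema; replace with transcribed published coefficients before scientific use."
  }
]
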