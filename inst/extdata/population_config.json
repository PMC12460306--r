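{
  "_comment": "Synthetic population-statistics fixture, structurally faithful to regional census-style tables for an urban south-western British Columbia population. All values are documented placeholders chosen to be plausible, not scraped statistics.",
  "reference_date": "2025-01-01",
  "ethnicity": {
    "labels": ["European", "Chinese", "South Asian", "Filipino", "Southeast Asian", "Korean", "Latin American", "Indigenous", "West Asian or Other"],
    "probs": [0.46, 0.19, 0.12, 0.05, 0.04, 0.03, 0.03, 0.04, 0.04]
  },
  "age_groups": {
    "labels": ["18-24", "25-34", "35-44", "45-54", "55-64"],
    "probs": [0.13, 0.22, 0.21, 0.19, 0.25],
    "bounds": [[18, 24], [25, 34], [35, 44], [45, 54], [55, 64]]
  },
  "sex": {
    "labels": ["female", "male"],
    "probs": [0.51, 0.49]
  },
  "relationship_by_age_sex": {
    "categories": ["Single", "Living-apart-together", "Married", "Common-law", "Divorced/Separated", "Widowed"],
    "rows": {
      "18-24|female": [0.72, 0.12, 0.05, 0.10, 0.01, 0.00],
      "18-24|male":   [0.78, 0.10, 0.03, 0.08, 0.01, 0.00],
      "25-34|female": [0.38, 0.10, 0.28, 0.20, 0.04, 0.00],
      "25-34|male":   [0.44, 0.10, 0.24, 0.18, 0.04, 0.00],
      "35-44|female": [0.20, 0.06, 0.48, 0.16, 0.09, 0.01],
      "35-44|male":   [0.24, 0.06, 0.46, 0.15, 0.09, 0.00],
      "45-54|female": [0.15, 0.05, 0.52, 0.12, 0.14, 0.02],
      "45-54|male":   [0.17, 0.05, 0.53, 0.11, 0.13, 0.01],
      "55-64|female": [0.11, 0.04, 0.52, 0.09, 0.18, 0.06],
      "55-64|male":   [0.12, 0.04, 0.56, 0.09, 0.17, 0.02]
    }
  },
  "parental_by_age_sex": {
    "18-24|female": 0.06, "18-24|male": 0.03,
    "25-34|female": 0.38, "25-34|male": 0.28,
    "35-44|female": 0.74, "35-44|male": 0.66,
    "45-54|female": 0.82, "45-54|male": 0.80,
    "55-64|female": 0.84, "55-64|male": 0.83
  },
  "disability_any_by_age_sex": {
    "18-24|female": 0.20, "18-24|male": 0.16,
    "25-34|female": 0.22, "25-34|male": 0.17,
    "35-44|female": 0.24, "35-44|male": 0.19,
    "45-54|female": 0.28, "45-54|male": 0.24,
    "55-64|female": 0.34, "55-64|male": 0.30
  },
  "disability_type_shares": {
    "labels": ["Mental-health related", "Pain-related", "Seeing", "Learning", "Memory", "Mobility", "Flexibility", "Hearing", "Dexterity", "Developmental"],
    "probs": [0.17, 0.22, 0.07, 0.08, 0.07, 0.12, 0.11, 0.07, 0.05, 0.04]
  },
  "name_locale_weights": {
    "labels": ["english", "chinese", "punjabi", "french"],
    "probs": [0.55, 0.20, 0.13, 0.12]
  },
  "catalog": {
    "condition_to_meds": {
      "Major depressive disorder": ["Sertraline 50 mg daily", "Escitalopram 10 mg daily", "Bupropion XL 150 mg daily"],
      "Generalized anxiety disorder": ["Escitalopram 10 mg daily", "Buspirone 10 mg twice daily", "Venlafaxine XR 75 mg daily"],
      "Bipolar II disorder": ["Lamotrigine 100 mg daily", "Quetiapine 50 mg nightly", "Lithium carbonate 600 mg daily"],
      "Post-traumatic stress disorder": ["Paroxetine 20 mg daily", "Prazosin 2 mg nightly"],
      "Attention-deficit/hyperactivity disorder": ["Methylphenidate ER 27 mg daily", "Lisdexamfetamine 30 mg daily"],
      "Obsessive-compulsive disorder": ["Fluoxetine 40 mg daily", "Fluvoxamine 100 mg daily"],
      "Panic disorder": ["Sertraline 100 mg daily", "Clonazepam 0.25 mg as needed"],
      "Social anxiety disorder": ["Sertraline 50 mg daily", "Propranolol 10 mg as needed"]
    },
    "unconstrained_lists": {
      "allergies": ["no known allergies", "penicillin", "peanuts", "shellfish", "seasonal pollen", "latex", "sulfa drugs", "cat dander"],
      "supplements": ["none", "vitamin D", "omega-3 fish oil", "a daily multivitamin", "magnesium", "melatonin", "iron", "vitamin B12"],
      "recreational_drugs": ["none", "alcohol socially", "cannabis occasionally", "nicotine vaping", "cigarettes", "alcohol and cannabis"],
      "visit_reason": ["low mood and loss of interest", "persistent worry and restlessness", "trouble sleeping for several months", "panic episodes at work", "difficulty concentrating at work", "conflict at home causing distress", "feeling burned out and tearful", "intrusive memories after an accident"]
    },
    "comorbidity": {
      "prob_any": 0.6,
      "count_weights": {"1": 0.6, "2": 0.3, "3": 0.1}
    }
  }
}
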