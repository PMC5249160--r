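{
  "metabolites": [
    {"id": "A"},
    {"id": "B"},
    {"id": "C"}
  ],
  "reactions": [
    {
      "id": "EX_A",
      "metabolites": {"A": -1},
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R1",
      "metabolites": {"A": -1, "B": 1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g1 and g2",
      "objective_coefficient": 0
    },
    {
      "id": "B1",
      "metabolites": {"A": -1, "B": 1},
      "lower_bound": 0,
      "upper_bound": 4,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R2",
      "metabolites": {"B": -1, "C": 1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g3 or g4",
      "objective_coefficient": 0
    },
    {
      "id": "GROWTH",
      "metabolites": {"C": -1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    {"id": "g1"}, {"id": "g2"}, {"id": "g3"}, {"id": "g4"}
  ]
}
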