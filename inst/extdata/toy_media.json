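{
  "reference": {
    "name": "minimal_glc_nh4",
    "uptake": {"EX_A": 10}
  },
  "carbon_exchange": "EX_A",
  "nitrogen_exchange": "EX_A",
  "rich_media": [
    {"name": "rich_open", "uptake": {"EX_A": "unbounded"}},
    {"name": "rich_capped", "uptake": {"EX_A": 20}}
  ]
}
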