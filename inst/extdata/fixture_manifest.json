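{
  "table3_external_validation.csv": "f486819cab43b5030aaf15a1ad0eb7cb",
  "table5_activities.csv": "f2776e064cf8bb3837b84b6c1717c292",
  "table10_properties.csv": "5c2120195b3dd7c56a76caeb46b40ca4",
  "published_models.json": "5985ea82794c28736be24401d1b817d7"
}
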