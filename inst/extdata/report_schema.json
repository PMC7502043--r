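{
  "title": "mtprep end-to-end metric report",
  "required_sections": ["provenance", "translational", "gmd"],
  "required_metrics": ["mtr_remote", "mtr_scar", "scar_threshold",
                       "overlap_percent", "false_positive_percent", "dice",
                       "global_mean_mtr", "contrast_ratio",
                       "vessel_sharpness", "cnr"]
}
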