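{
  "title": "Harmonised multi-stressor observation schema",
  "description": "One row per study x treatment arm x time point. Arm summary statistics are stored wide as <response>_{mean,sd,n}_{c,t} for the control (c) and treatment (t) arm. Shannon columns are optional; stressor_level may be replaced by stressor_levels, a comma list aligned with stressor_ids.",
  "columns": {
    "study_id": {"type": "string", "description": "Study identifier; the random-effect grouping unit."},
    "observation_id": {"type": "string", "description": "Unique identifier of the study x arm observation."},
    "arm_id": {"type": "string", "description": "Treatment arm label, e.g. 'A' or 'A+B'."},
    "organism_group": {"type": "string", "enum": ["heterotrophic microorganisms", "algae", "zooplankton", "macroinvertebrates"], "description": "Broad organism group the responses belong to."},
    "function_type": {"type": "string", "enum": ["biomass", "leaf decomposition", "photosynthesis", "production"], "description": "Ecosystem function (or proxy) type; must be attributable a priori to the organism group."},
    "stressor_ids": {"type": "string", "description": "Comma-separated stressor identifiers acting in this arm."},
    "stressor_categories": {"type": "string", "description": "Categories of those stressors, from {habitat, nutrients, water quality}."},
    "stressor_combination": {"type": "string", "description": "Label of the stressor-category combination (nested within n_stressors in the model)."},
    "n_stressors": {"type": "integer", "minimum": 1, "description": "Number of distinct stressors in the arm."},
    "stressor_level": {"type": "number", "description": "Intensity level of the arm's stressor(s); the analysis keeps only the highest level per study x stressor."},
    "phase": {"type": "string", "enum": ["pre", "post"], "description": "Measurement phase relative to stressor exposure; pre-exposure rows are dropped."},
    "time_point": {"type": "integer", "description": "Post-exposure time point index; aggregated by the pipeline."},
    "richness_mean_c": {"type": "number", "description": "Control-arm mean taxon richness."},
    "richness_sd_c": {"type": "number", "minimum": 0},
    "richness_n_c": {"type": "integer", "minimum": 1},
    "richness_mean_t": {"type": "number", "description": "Treatment-arm mean taxon richness."},
    "richness_sd_t": {"type": "number", "minimum": 0},
    "richness_n_t": {"type": "integer", "minimum": 1},
    "shannon_mean_c": {"type": "number", "description": "Optional: control-arm mean Shannon diversity."},
    "shannon_sd_c": {"type": "number", "minimum": 0},
    "shannon_n_c": {"type": "integer", "minimum": 1},
    "shannon_mean_t": {"type": "number"},
    "shannon_sd_t": {"type": "number", "minimum": 0},
    "shannon_n_t": {"type": "integer", "minimum": 1},
    "function_mean_c": {"type": "number", "description": "Control-arm mean of the ecosystem-function response, in the study's units (consistent within a row)."},
    "function_sd_c": {"type": "number", "minimum": 0},
    "function_n_c": {"type": "integer", "minimum": 1},
    "function_mean_t": {"type": "number"},
    "function_sd_t": {"type": "number", "minimum": 0},
    "function_n_t": {"type": "integer", "minimum": 1}
  }
}
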