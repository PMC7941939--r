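# Imputation specification: which variables are imputed, with which
# conditional model, and at which level (within each cluster, or pooled
# across clusters for variables some sites cannot supply at all).
predictors:
  - site
  - mat_h_height
  - mat_h_weight
  - mat_h_ethnicity
  - mat_h_parity
  - outcome_triple
  - age_at_delivery
  - mat_h_ga
m: 10
iterations: 10
pmm_k: 5
variables:
  mat_h_height: {family: pmm, scope: across_clusters}
  mat_h_weight: {family: pmm, scope: across_clusters}
  mat_h_parity: {family: pmm_round, scope: across_clusters}
  mat_h_ethnicity: {family: multinomial, scope: within_cluster}
  outcome_triple: {family: multinomial, scope: within_cluster}
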