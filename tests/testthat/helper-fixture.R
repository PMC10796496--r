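# shared fixture objects, built once per test run
fx_grouped <- cerehetis_cohort()
fx_units <- expand_cohort(fx_grouped)

fit_sht <- fit_logit(sht ~ arm + hti, fx_units)
fit_ffo <- fit_logit(ffo ~ arm + hti, fx_units)
fit_aht <- fit_logit(any_ht ~ arm + hti, fx_units)

# simple inverse-logit for hand computations
invlogit <- function(x) 1 / (1 + exp(-x))
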