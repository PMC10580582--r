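# shared fixtures built in code at test time

table1_dists <- function() {
  list(
    ni_pfs = parametric_survival("log_normal", 1.93843, 1.26135),
    c_pfs  = parametric_survival("log_logistic", 7.53780, 2.29427),
    ni_os_a = parametric_survival("weibull_ph", 0.0241553, 1.1284343),
    c_os_a  = parametric_survival("log_logistic", 14.25065, 1.76236),
    ni_os_n = parametric_survival("exponential", 0.0412831),
    c_os_n  = parametric_survival("log_logistic", 9.03382, 2.17796))
}

all_family_examples <- function() {
  list(
    exponential  = parametric_survival("exponential", 0.0412831),
    weibull_ph   = parametric_survival("weibull_ph", 0.0241553, 1.1284343),
    log_logistic = parametric_survival("log_logistic", 14.25065, 1.76236),
    log_normal   = parametric_survival("log_normal", 1.93843, 1.26135),
    gompertz     = parametric_survival("gompertz", 0.03, 0.02),
    gamma        = parametric_survival("gamma", 0.08, 1.4))
}

# deterministic base configuration without the reconstructed-gamma message
quiet_base_case <- function(...) suppressMessages(run_base_case(...))
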