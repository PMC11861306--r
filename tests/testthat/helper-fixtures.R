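# central-side (zero-velocity) baseline used throughout the tests: generalized
# three-compartment fatigue/recovery constants and the conventional gain
baseline_fixed <- function() list(FC0 = 0.00912, RC0 = 0.00094, r = 7.5, L = 20)

# parameters with the velocity-dependent triple taken from a calibrated
# muscle group's row (see muscle_group_parameters())
group_params <- function(group, fixed = baseline_fixed()) {
  mg <- muscle_group_parameters()
  row <- mg[mg$muscle_group == group, ]
  fatigue_parameters(FC0 = fixed$FC0, FP0 = row$FP0, RC0 = fixed$RC0,
                     RP0 = row$RP0, r = fixed$r, k = row$k, L = fixed$L,
                     muscle_group = group)
}

# the velocity triple of a calibrated group as a named vector
group_triple <- function(group) {
  mg <- muscle_group_parameters()
  row <- mg[mg$muscle_group == group, ]
  c(k = row$k, RP0 = row$RP0, FP0 = row$FP0)
}

joint_of <- function(group) strsplit(group, " ")[[1]][1]
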