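# Shared helpers for the suite.
#
# Relative error with a one-cell floor: components are compared relatively
# when at least one exceeds one cell, absolutely (in cells) below that —
# sub-cell counts are beneath the resolution of a deterministic
# continuous-count model.
rel_err <- function(a, b, floor = 1) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

state_vec <- function(state) as.numeric(state[c("w", "x", "y", "z")])

# default inputs used across tests
tbl <- default_parameter_table()
std <- standard_initial_state()

# independent dense-scan recurrence oracle: first 0.1-day grid point at or
# above baseline after the total has been strictly below it (no
# interpolation — deliberately a different detector)
dense_recurrence <- function(params, schedule, initial = std, by = 0.1) {
  traj <- simulate_schedule(params, schedule, initial, output_step = by)
  baseline <- traj$total[1]
  below <- which(traj$total < baseline)
  if (length(below) == 0) return(NA_real_)
  after <- which(traj$total >= baseline & seq_along(traj$total) > below[1])
  if (length(after) == 0) return(NA_real_)
  traj$time[after[1]]
}
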