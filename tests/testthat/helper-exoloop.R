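# shared fixtures: classifiers are expensive to train, so they are built once
# per test run and cached
.sim_cache <- new.env(parent = emptyenv())

# the full prior-dataset classifier used by the end-to-end optimization checks
full_classifier <- function() {
  if (is.null(.sim_cache$full)) {
    tp <- simulate_prior_dataset(seed = 501)
    .sim_cache$full <- train_classifier(tp)
  }
  .sim_cache$full
}

# a reduced classifier for module-level checks
small_classifier <- function() {
  if (is.null(.sim_cache$small)) {
    tp <- simulate_prior_dataset(n_participants = 2, n_conditions = 30, seed = 77)
    .sim_cache$small <- train_classifier(tp)
  }
  .sim_cache$small
}

make_constant_strides <- function(n, angle = 5, vel = 2, period = 1.1, m = 60,
                                  bout_id = 1L, law_id = 1L) {
  lapply(seq_len(n), function(i)
    stride_record(rep(angle, m), rep(vel, m), period, bout_id, law_id))
}

# ground-truth ranking oracle for real-world sessions (ranks evaluated laws by
# their true outdoor metabolic rate)
oracle_ranker <- function(participant, speed = 1.3) {
  function(feats) {
    vals <- vapply(feats, function(f) {
      tp <- f$torque_params
      metabolic_rate(participant,
                     control_law(tp[1], tp[2], tp[3], tp[4], validate = FALSE),
                     speed, context = "outdoor")
    }, numeric(1))
    rank_by_value(vals)
  }
}
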