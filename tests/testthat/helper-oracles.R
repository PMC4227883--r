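# Independent oracles and small fixture builders shared across tests.

# Naive state-machine reading of the two-threshold bouton rule, written
# directly from the rule's verbal statement; kept independent of
# classify_bouton_series().
oracle_hysteresis <- function(ratios, appear = 3.0, persist = 1.3) {
  present <- FALSE
  out <- integer(length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    if (!present && r >= appear) present <- TRUE
    else if (present && r < persist) present <- FALSE
    out[i] <- as.integer(present)
  }
  out
}

# Tidy records for a hand-specified presence pattern set. `patterns` is a
# named list: structure_id -> integer vector over `days`.
records_from_patterns <- function(patterns, days = c(0, 4, 8, 12),
                                  animal_id = "a1") {
  do.call(rbind, lapply(names(patterns), function(id) {
    data.frame(animal_id = animal_id, field_id = "f1", structure_id = id,
               session_day = days, present = patterns[[id]],
               stringsAsFactors = FALSE)
  }))
}

pm_from_patterns <- function(patterns, days = c(0, 4, 8, 12),
                             policy = "split", animal_id = "a1") {
  build_presence_matrix(records_from_patterns(patterns, days, animal_id),
                        policy = policy)
}

# Closed-form survival of the two-population mixture at offset k intervals.
two_pop_survival <- function(k, f_p, s_p, s_t) {
  f_p * s_p^k + (1 - f_p) * s_t^k
}
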