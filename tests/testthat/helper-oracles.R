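# Independent oracles used across test files.

# Explicit transition-matrix recursion for the three-state model:
# state order (no_hl, hl, dead); per cycle, death probability q[t] applies
# to both alive states, then the conditional conversion h[t] moves
# surviving no-HL members to HL.
hand_recursion <- function(q, h) {
  n <- length(q)
  out <- matrix(0, n + 1, 3,
                dimnames = list(NULL, c("p_no_hl", "p_hl", "p_dead")))
  out[1, ] <- c(1, 0, 0)
  for (t in seq_len(n)) {
    M <- matrix(c(
      (1 - q[t]) * (1 - h[t]), (1 - q[t]) * h[t], q[t],
      0,                        1 - q[t],          q[t],
      0,                        0,                 1), 3, 3, byrow = TRUE)
    out[t + 1, ] <- out[t, ] %*% M
  }
  out
}

# build a state_trace data frame by hand
make_trace <- function(t, p_no_hl, p_hl, p_dead, start_age = 6) {
  structure(data.frame(t = t, age = start_age + t, p_no_hl = p_no_hl,
                       p_hl = p_hl, p_dead = p_dead),
            class = c("state_trace", "data.frame"))
}

# a zero-mortality life table over ages 0-100
zero_life_table <- function() {
  validate_life_table(data.frame(age = 0:100, qx = 0))
}

# collapse every triangular range to a point at the current base value
degenerate_ranges <- function(p) {
  acc <- protonCEA:::range_accessors()
  for (nm in names(p$ranges)) {
    b <- acc[[nm]]$get(p)
    p$ranges[[nm]] <- list(low = b, high = b)
  }
  p
}
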