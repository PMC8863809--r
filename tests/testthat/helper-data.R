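# Small in-code fixtures shared across tests.

# interaction log from a compact record list
make_log <- function(records, effort) {
  structure(list(
    records = do.call(rbind, lapply(records, function(r)
      data.frame(month = r[[1]], actor = r[[2]], receiver = r[[3]],
                 kind = r[[4]], count = r[[5]], stringsAsFactors = FALSE))),
    effort = data.frame(subject_id = names(effort),
                        total_occurrences = unname(effort),
                        stringsAsFactors = FALSE)),
    class = "ts_interaction_log")
}

# picture table for a single event
make_pictures <- function(event_id, angles, temps, secs = NULL,
                          subject = "M01") {
  data.frame(event_id = event_id, subject_id = subject, angle = angles,
             temp_c = temps,
             sec_after_event = secs %||% rep(60, length(angles)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a quiet generator run at reduced size for structural tests
small_dataset <- function(seed = 1, ...) {
  generate_dataset(generator_config(seed = seed, n_events_per_type = 8,
                                    n_baseline_events = 40,
                                    months_longterm = 2, ...))
}

# brute-force greedy Ward agglomeration; heights on the ward.D2 scale
brute_force_ward <- function(X) {
  cl <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  cost <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(X[a, , drop = FALSE])
    cb <- colMeans(X[b, , drop = FALSE])
    na * nb / (na + nb) * sum((ca - cb)^2)
  }
  while (length(cl) > 1) {
    best <- c(NA, NA); bc <- Inf
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      cc <- cost(cl[[i]], cl[[j]])
      if (cc < bc) { bc <- cc; best <- c(i, j) }
    }
    heights <- c(heights, sqrt(2 * bc))
    cl <- c(cl[-best], list(c(cl[[best[1]]], cl[[best[2]]])))
  }
  heights
}
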