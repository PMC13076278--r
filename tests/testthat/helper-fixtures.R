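# Small fixtures shared across test files. All built in code.

# state panel from a matrix of per-region state sequences (rows = regions)
state_panel <- function(seq_mat, n_states = 3, start_year = 2001) {
  n <- nrow(seq_mat); T_ <- ncol(seq_mat)
  ids <- sprintf("R%02d", seq_len(n))
  out <- data.frame(region_id = rep(ids, each = T_),
                    year = rep(start_year + seq_len(T_) - 1L, n),
                    state = as.vector(t(seq_mat)))
  attr(out, "threshold_spec") <- list(thresholds = rep(NA_real_,
                                                       n_states - 1),
                                      scheme = "fixture",
                                      n_states = n_states)
  out
}

random_dea_instance <- function(n_max = 6, m_max = 2, s_max = 2) {
  n <- sample(2:n_max, 1)
  m <- sample(seq_len(m_max), 1)
  s <- sample(seq_len(s_max), 1)
  list(X = matrix(exp(rnorm(n * m, 1, 0.8)), n, m),
       Y = matrix(exp(rnorm(n * s, 1, 0.8)), n, s),
       unit = sample(n, 1))
}

# sample() treats a scalar first argument as 1:x; this never does
pick_one <- function(x) x[sample.int(length(x), 1)]

two_group_map <- function(ids) {
  data.frame(region_id = ids,
             group = rep(c("A", "B"), length.out = length(ids)))
}
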