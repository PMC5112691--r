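# Independent brute-force recomputations of every statistic the package
# implements, written deliberately with loops over raw codes so they
# share no code path with the package internals.

oracle_intermediate <- function(codes) {
  vals <- c(yes = 1, no = 0, unsure = 0.5)
  got <- codes[codes != "unaware"]
  if (length(got) == 0) {
    return(list(value = NA_real_, n_received = 0L))
  }
  total <- 0
  for (c in got) total <- total + vals[[c]]
  list(value = 100 * total / length(got), n_received = length(got))
}

oracle_priority <- function(values) {
  defined <- values[!is.na(values)]
  if (length(defined) == 0) return(NA_real_)
  sum(defined) / length(defined)
}

oracle_mode_fraction <- function(codes) {
  best <- 0
  for (c in unique(codes)) {
    n_c <- sum(codes == c)
    if (n_c > best) best <- n_c
  }
  best / length(codes)
}

# slice: scorers x criteria character matrix of codes for one suggestion
oracle_suggestion <- function(slice) {
  ints <- numeric(0)
  fracs <- numeric(0)
  for (j in seq_len(ncol(slice))) {
    ints <- c(ints, oracle_intermediate(slice[, j])$value)
    fracs <- c(fracs, oracle_mode_fraction(slice[, j]))
  }
  list(intermediates = ints, priority = oracle_priority(ints),
       aea = mean(fracs))
}

# Build a complete response_matrix from a 3-d array of codes indexed
# [scorer, suggestion, criterion].
matrix_from_array <- function(arr, kind = "problem",
                              criteria = paste0("c", seq_len(dim(arr)[3]))) {
  scorers <- paste0("sc", seq_len(dim(arr)[1]))
  suggestions <- paste0("sug", seq_len(dim(arr)[2]))
  cells <- expand.grid(scorer_id = scorers, suggestion_id = suggestions,
                       criterion_id = criteria,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$response <- as.vector(arr)
  response_matrix(cells, kind, scorers = scorers, suggestions = suggestions,
                  criteria = criteria)
}

# Uniform-random complete matrix (for property tests under a fixed seed).
random_matrix <- function(n_scorers, n_suggestions, n_criteria,
                          kind = "problem",
                          probs = c(0.4, 0.2, 0.2, 0.2)) {
  codes <- sample(response_codes(), n_scorers * n_suggestions * n_criteria,
                  replace = TRUE, prob = probs)
  arr <- array(codes, dim = c(n_scorers, n_suggestions, n_criteria))
  matrix_from_array(arr, kind)
}

# Criterion sets sized to match the test matrices.
test_criteria <- function(n, kind = "problem") {
  criterion_set(kind, data.frame(id = paste0("c", seq_len(n)),
                                 statement = paste("criterion", seq_len(n))))
}
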