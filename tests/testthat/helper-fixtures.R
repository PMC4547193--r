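# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (explicit loops, brute force) and never share code with
# the implementation paths they check.

# random result table with discrete values so ties occur
make_random_table <- function(n_rows, n_params = 2L, n_measures = 3L,
                              seed = 1L) {
  set.seed(seed)
  df <- data.frame(record_id = seq_len(n_rows))
  pn <- paste0("p", seq_len(n_params))
  mn <- paste0("m", seq_len(n_measures))
  for (p in pn) df[[p]] <- sample(seq(0, 1, by = 0.25), n_rows, replace = TRUE)
  for (m in mn) df[[m]] <- round(stats::rnorm(n_rows), 1)
  result_table(df, param_columns = pn, measure_columns = mn)
}

# brute-force lexicographic sort oracle: selection sort with an explicit
# row comparator (earlier keys outermost, ties by record_id)
oracle_lex_sort <- function(df, keys) {
  less <- function(i, j) {
    for (k in keys) {
      if (df[[k]][i] < df[[k]][j]) return(TRUE)
      if (df[[k]][i] > df[[k]][j]) return(FALSE)
    }
    df$record_id[i] < df$record_id[j]
  }
  idx <- seq_len(nrow(df))
  for (a in seq_along(idx)) {
    best <- a
    b <- a + 1L
    while (b <= length(idx)) {
      if (less(idx[b], idx[best])) best <- b
      b <- b + 1L
    }
    tmp <- idx[a]; idx[a] <- idx[best]; idx[best] <- tmp
  }
  idx
}

# Pearson correlation from the defining sums (independent of stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(0)
  num / den
}

oracle_smart_choice <- function(table) {
  vis <- visible_records(table)
  scores <- vapply(table$param_columns, function(p) {
    rs <- vapply(table$measure_columns, function(m)
      abs(oracle_pearson(vis[[p]], vis[[m]])), numeric(1))
    mean(rs)
  }, numeric(1))
  table$param_columns[which.max(scores)]
}

# maximal-run oracle: walk outwards from the cursor position
oracle_context_run <- function(values, pos) {
  lo <- pos; hi <- pos
  while (lo > 1L && values[lo - 1L] == values[pos]) lo <- lo - 1L
  while (hi < length(values) && values[hi + 1L] == values[pos]) hi <- hi + 1L
  lo:hi
}

# small two-image deconvolution sweep used by several test files
make_deconv_sweep <- function(out_dir, n_samples = 3L, shape = c(48, 48),
                              seed = 1L) {
  specs <- list(parameter_spec("p1", -0.5, 0.5, n_samples),
                parameter_spec("p2", -0.5, 0.5, n_samples))
  imgs <- lapply(1:2, function(i)
    generate_two_stain_image(generate_structured_densities(
      shape = shape, n_blobs = c(6, 3), seed = seed + i - 1L))$image)
  run_sweep(specs, imgs, deconvolution_plugin(), seed = seed,
            out_dir = out_dir)
}
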