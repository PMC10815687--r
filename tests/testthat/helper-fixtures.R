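# Noise-free cohort configuration: depth effectively constant, GQ exact,
# no missingness, no recombination unless asked for.
clean_config <- function(...) {
  args <- list(...)
  defaults <- list(dp_size = 1e6, gq_sd = 0, missing_rate = 0,
                   recombinant_rate = 0)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Long call tibble from a samples x variants dosage matrix.
make_calls <- function(dosage, pos = NULL, chrom = "chr17",
                       dp = 30L, gq = 99L, ref = "A", alt = "G",
                       is_indel = FALSE) {
  n <- nrow(dosage); v <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%03d", seq_len(v))
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = v)
  dp <- matrix(dp, n, v); gq <- matrix(gq, n, v)
  is_indel <- rep_len(is_indel, v); ref <- rep_len(ref, v); alt <- rep_len(alt, v)
  tibble::tibble(
    sample_id = rep(rownames(dosage), times = v),
    variant_id = rep(colnames(dosage), each = n),
    chrom = chrom,
    pos = rep(pos, each = n),
    ref = rep(ref, each = n),
    alt = rep(alt, each = n),
    is_indel = rep(is_indel, each = n),
    dosage = as.integer(dosage),
    dp = as.integer(dp),
    gq = as.integer(gq)
  )
}

# Independent Pearson r^2 oracle: explicit sum arithmetic, no cor().
r2_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  cov <- sum(x * y) - sx * sy / n
  vx <- sum(x^2) - sx^2 / n
  vy <- sum(y^2) - sy^2 / n
  cov^2 / (vx * vy)
}

# Planted inner divergent block for a config with two default breakpoints:
# divergent positions strictly between the breakpoints.
planted_inner_block <- function(config) {
  vars <- h2scan:::cohort_variants(config)
  dv <- sort(vars$pos[vars$role == "divergent"])
  bp <- config$recombinant_breakpoints
  dv <- dv[dv > min(bp) & dv < max(bp)]
  c(min(dv), max(dv))
}
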