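# Pairwise dependence: binned mutual information (nats), Pearson correlation,
# and permutation-test significance, all on pairwise-complete observations.

# Keep only rows where both values are present.
complete_pairs <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Default number of equal-width bins for a continuous variable
#'
#' `ceiling(sqrt(n/5))`, bounded to `[2, 10]`: coarse enough that expected
#' cell counts stay usable at cohort sample sizes.
#'
#' @param n number of pairwise-complete observations.
#' @return integer bin count.
#' @export
default_bins <- function(n) {
  max(2L, min(10L, as.integer(ceiling(sqrt(n / 5)))))
}

# Integer bin codes (1..n_codes) for one variable. Continuous variables get
# equal-width bins over the observed (pairwise-complete) range; discrete
# kinds use their observed levels. A constant vector maps to a single code.
bin_codes <- function(v, kind = "continuous", n_bins = NULL) {
  if (kind == "continuous") {
    rng <- range(v)
    if (rng[1] == rng[2]) return(list(codes = rep(1L, length(v)), n = 1L))
    if (is.null(n_bins)) n_bins <- default_bins(length(v))
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    codes <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    list(codes = as.integer(codes), n = as.integer(n_bins))
  } else {
    lev <- sort(unique(v))
    list(codes = match(v, lev), n = length(lev))
  }
}

#' Binned mutual information
#'
#' Plug-in histogram estimate of I(X;Y) in nats: the supports are partitioned
#' into bins, joint and marginal probabilities are estimated by relative
#' counts, and cells with zero joint count contribute nothing. Computed on
#' pairwise-complete observations only.
#'
#' @param x,y value vectors of equal length (`NA` = missing).
#' @param n_bins bin count for continuous variables; default
#'   [default_bins()] of the pairwise-complete sample size.
#' @param kind_x,kind_y value kinds (`"continuous"`, `"binary"`,
#'   `"categorical"`, `"ordinal"`); discrete kinds use observed levels as bins.
#' @return non-negative mutual information in nats; 0 for a constant input.
#' @export
mutual_information_binned <- function(x, y, n_bins = NULL,
                                      kind_x = "continuous",
                                      kind_y = "continuous") {
  stopifnot(length(x) == length(y))
  cp <- complete_pairs(x, y)
  if (cp$n < 2L) stop("insufficient data: fewer than 2 complete pairs")
  bx <- bin_codes(cp$x, kind_x, n_bins)
  by <- bin_codes(cp$y, kind_y, n_bins)
  cpp_mi_nats(bx$codes, by$codes, bx$n, by$n)
}

# Entropy (nats) of a code vector.
entropy_nats <- function(codes) {
  p <- tabulate(codes)
  p <- p[p > 0] / length(codes)
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' `I(X;Y) / sqrt(H(X) * H(Y))` with entropies estimated on the same binning,
#' clipped to `[0, 1]`; 0 when either entropy is 0.
#'
#' @inheritParams mutual_information_binned
#' @return normalized mutual information in `[0, 1]`.
#' @export
normalized_mi <- function(x, y, n_bins = NULL,
                          kind_x = "continuous", kind_y = "continuous") {
  stopifnot(length(x) == length(y))
  cp <- complete_pairs(x, y)
  if (cp$n < 2L) stop("insufficient data: fewer than 2 complete pairs")
  bx <- bin_codes(cp$x, kind_x, n_bins)
  by <- bin_codes(cp$y, kind_y, n_bins)
  hx <- entropy_nats(bx$codes)
  hy <- entropy_nats(by$codes)
  if (hx == 0 || hy == 0) return(0)
  mi <- cpp_mi_nats(bx$codes, by$codes, bx$n, by$n)
  min(1, max(0, mi / sqrt(hx * hy)))
}

#' Pearson correlation on pairwise-complete rows
#'
#' @param x,y value vectors of equal length (`NA` = missing).
#' @return product-moment coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  cp <- complete_pairs(x, y)
  if (cp$n < 2L) stop("insufficient data: fewer than 2 complete pairs")
  if (sd(cp$x) == 0 || sd(cp$y) == 0)
    stop("undefined correlation: constant input")
  cor(cp$x, cp$y)
}

#' Permutation p-value for a pair statistic
#'
#' Permutes `y` over the pairwise-complete rows `n_perm` times and applies
#' the add-one estimator `p = (1 + #{permuted >= observed}) / (1 + n_perm)`.
#' MI is one-tailed (dependence only); Pearson is two-tailed (comparison on
#' absolute values). Deterministic given `seed`.
#'
#' @param x,y value vectors (`NA` = missing).
#' @param stat `"mi"`, `"pearson"`, or a function `f(x, y)` of complete pairs.
#' @param n_perm number of permutations (default 1000).
#' @param tails `"one"` or `"two"`; fixed for the named statistics, honoured
#'   for function statistics.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @inheritParams mutual_information_binned
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, stat = c("mi", "pearson"), n_perm = 1000L,
                               tails = NULL, seed = NULL, n_bins = NULL,
                               kind_x = "continuous", kind_y = "continuous") {
  stopifnot(length(x) == length(y), n_perm >= 1)
  cp <- complete_pairs(x, y)
  if (cp$n < 2L) stop("insufficient data: fewer than 2 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  if (is.function(stat)) {
    if (is.null(tails)) tails <- "one"
    obs <- stat(cp$x, cp$y)
    perm <- vapply(seq_len(n_perm),
                   function(i) stat(cp$x, sample(cp$y)), numeric(1))
    count <- if (tails == "two") sum(abs(perm) >= abs(obs)) else sum(perm >= obs)
  } else {
    stat <- match.arg(stat)
    if (stat == "mi") {
      bx <- bin_codes(cp$x, kind_x, n_bins)
      by <- bin_codes(cp$y, kind_y, n_bins)
      count <- cpp_perm_count_mi(bx$codes, by$codes, bx$n, by$n, as.integer(n_perm))
    } else {
      if (sd(cp$x) == 0 || sd(cp$y) == 0)
        stop("undefined correlation: constant input")
      count <- cpp_perm_count_pearson(cp$x, cp$y, as.integer(n_perm))
    }
  }
  (1 + count) / (1 + n_perm)
}

#' Pairwise association table for a cohort
#'
#' Computes, for every requested variable pair, the pairwise-complete sample
#' size, binned MI (nats), normalized MI, Pearson r, and permutation
#' p-values (one-tailed for MI, two-tailed for Pearson). Per-pair seeds are
#' derived from the master seed and the pair name, so pairs are reproducible
#' and mutually independent.
#'
#' @param cohort a `cohort` object.
#' @param pairs optional 2-column character matrix/data.frame of variable
#'   pairs; default all unordered pairs.
#' @param n_perm permutations per test.
#' @param n_bins continuous bin count (default [default_bins()]).
#' @param seed master integer seed.
#' @param stats which permutation tests to run (`"mi"`, `"pearson"`, or
#'   both); the point statistics are always computed, untested p-values stay
#'   `NA`.
#' @return data.frame: var_a, var_b, layer_a, layer_b, n_complete, mi, nmi,
#'   r, p_mi, p_r. `r` and `p_r` are `NA` for pairs with a constant member.
#' @export
association_table <- function(cohort, pairs = NULL, n_perm = 1000L,
                              n_bins = NULL, seed = 1L,
                              stats = c("mi", "pearson")) {
  stats <- match.arg(stats, several.ok = TRUE)
  meta <- cohort$meta
  if (is.null(pairs)) {
    pairs <- t(combn(meta$variable, 2L))
  } else {
    pairs <- as.matrix(pairs)
  }
  m <- nrow(pairs)
  res <- data.frame(
    var_a = pairs[, 1L], var_b = pairs[, 2L],
    layer_a = meta$layer[match(pairs[, 1L], meta$variable)],
    layer_b = meta$layer[match(pairs[, 2L], meta$variable)],
    n_complete = NA_integer_, mi = NA_real_, nmi = NA_real_, r = NA_real_,
    p_mi = NA_real_, p_r = NA_real_, stringsAsFactors = FALSE)
  kinds <- meta$kind[match(c(pairs), meta$variable)]
  dim(kinds) <- dim(pairs)
  for (i in seq_len(m)) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    cp <- complete_pairs(cohort$data[[a]], cohort$data[[b]])
    res$n_complete[i] <- cp$n
    if (cp$n < 2L) next
    bx <- bin_codes(cp$x, kinds[i, 1L], n_bins)
    by <- bin_codes(cp$y, kinds[i, 2L], n_bins)
    res$mi[i] <- cpp_mi_nats(bx$codes, by$codes, bx$n, by$n)
    hx <- entropy_nats(bx$codes); hy <- entropy_nats(by$codes)
    res$nmi[i] <- if (hx == 0 || hy == 0) 0 else
      min(1, max(0, res$mi[i] / sqrt(hx * hy)))
    if ("mi" %in% stats) {
      set.seed(derive_seed(seed, paste0("mi:", a, ":", b)))
      res$p_mi[i] <- (1 + cpp_perm_count_mi(bx$codes, by$codes, bx$n, by$n,
                                            as.integer(n_perm))) / (1 + n_perm)
    }
    if (sd(cp$x) > 0 && sd(cp$y) > 0) {
      res$r[i] <- cor(cp$x, cp$y)
      if ("pearson" %in% stats) {
        set.seed(derive_seed(seed, paste0("r:", a, ":", b)))
        res$p_r[i] <- (1 + cpp_perm_count_pearson(cp$x, cp$y,
                                                  as.integer(n_perm))) / (1 + n_perm)
      }
    }
  }
  res
}

#' Write an association table as tab-delimited text
#'
#' @param assoc result of [association_table()].
#' @param file output path.
#' @export
write_association_table <- function(assoc, file) {
  write.table(assoc, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
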