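# Synthetic cohort generator: latent-Gaussian factor model over six layers
# with mixed variable kinds, per-layer missingness, within-layer correlated
# blocks, and planted cross-layer dependency chains.

#' Define a layer of a synthetic cohort
#'
#' @param name layer name (e.g. `"genetic"`).
#' @param n_variables number of variables in the layer.
#' @param kinds character vector of value kinds, recycled to `n_variables`;
#'   each of `"continuous"`, `"binary"`, `"categorical"`, `"ordinal"`.
#' @param n_levels number of levels for categorical/ordinal variables.
#' @return a `layer_def` list.
#' @export
layer_def <- function(name, n_variables, kinds = "continuous", n_levels = 3L) {
  stopifnot(is.character(name), length(name) == 1L, n_variables >= 1)
  kinds <- match.arg(kinds, c("continuous", "binary", "categorical", "ordinal"),
                     several.ok = TRUE)
  kinds <- rep_len(kinds, n_variables)
  structure(list(name = name, n_variables = as.integer(n_variables),
                 kinds = kinds, n_levels = as.integer(n_levels)),
            class = "layer_def")
}

#' Define a within-layer correlated block
#'
#' Variables in a block share a latent factor with the given loading, so the
#' population Pearson correlation between two block members is `loading^2`
#' (at `noise_sd = 1`).
#'
#' @param layer layer name.
#' @param size number of variables in the block.
#' @param loading latent loading in (0, 1].
#' @return a `block_def` list.
#' @export
block_def <- function(layer, size, loading) {
  stopifnot(size >= 2, loading > 0, loading <= 1)
  structure(list(layer = layer, size = as.integer(size), loading = loading),
            class = "block_def")
}

#' Define a planted cross-layer dependency chain
#'
#' Chain latents propagate sequentially: each variable's latent is
#' `strength` times the previous chain variable's latent plus independent
#' noise, so consecutive chain pairs have population correlation `strength`
#' and correlation decays as `strength^d` with chain distance `d`.
#'
#' @param variables ordered character vector of variable names, one per
#'   traversed layer, ending at the phenotype layer by convention.
#' @param strength latent loading in (0, 1].
#' @param group optional diagnostic group name; if given, the chain
#'   dependence is planted only in subjects of that group.
#' @return a `chain_def` list.
#' @export
chain_def <- function(variables, strength, group = NULL) {
  stopifnot(length(variables) >= 2, anyDuplicated(variables) == 0,
            strength > 0, strength <= 1)
  structure(list(variables = as.character(variables), strength = strength,
                 group = group), class = "chain_def")
}

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param layers list of [layer_def()] objects.
#' @param group_fractions named proportions over diagnostic groups, summing
#'   to 1. Defaults to the control/MCI/AD mix of a typical ADNI-style cohort
#'   (622/807/533 of 1962).
#' @param missingness named per-layer probability that a subject's entire
#'   layer is missing (missing-completely-at-random, per subject x layer).
#' @param blocks list of [block_def()] objects.
#' @param chains list of [chain_def()] objects.
#' @param noise_sd residual standard deviation multiplier (default 1; the
#'   closed forms `r = loading^2` and `r = strength` hold at 1).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, layers,
                        group_fractions = c(control = 622, MCI = 807, AD = 533) / 1962,
                        missingness = NULL, blocks = list(), chains = list(),
                        noise_sd = 1, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("invalid 'n_subjects'")
  if (!is.list(layers) || length(layers) == 0L)
    stop("invalid 'layers': need at least one layer_def")
  layer_names <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(layer_names)) stop("invalid 'layers': duplicated layer names")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("invalid 'group_fractions': must sum to 1")
  if (is.null(missingness)) {
    missingness <- stats::setNames(rep(0, length(layer_names)), layer_names)
  }
  if (is.null(names(missingness)) || !all(names(missingness) %in% layer_names))
    stop("invalid 'missingness': names must be layer names")
  missingness <- missingness[match(layer_names, names(missingness))]
  missingness[is.na(missingness)] <- 0
  names(missingness) <- layer_names
  if (any(missingness < 0 | missingness > 1))
    stop("invalid 'missingness': probabilities must lie in [0, 1]")
  if (noise_sd <= 0) stop("invalid 'noise_sd': must be positive")

  spec <- structure(
    list(n_subjects = as.integer(n_subjects), layers = layers,
         group_fractions = group_fractions, missingness = missingness,
         blocks = blocks, chains = chains, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
  meta <- spec_metadata(spec)  # also validates blocks/chains against layers
  spec$.meta <- meta
  spec
}

# Lay out variables: names, layers, kinds, and block/chain assignments.
spec_metadata <- function(spec) {
  meta <- do.call(rbind, lapply(spec$layers, function(ld) {
    data.frame(variable = sprintf("%s_%02d", ld$name, seq_len(ld$n_variables)),
               layer = ld$name, kind = ld$kinds, n_levels = ld$n_levels,
               stringsAsFactors = FALSE)
  }))
  meta$block <- NA_integer_
  meta$chain <- NA_integer_

  for (ci in seq_along(spec$chains)) {
    ch <- spec$chains[[ci]]
    idx <- match(ch$variables, meta$variable)
    if (anyNA(idx))
      stop("invalid 'chains': unknown variable(s) ",
           paste(ch$variables[is.na(idx)], collapse = ", "))
    if (any(!is.na(meta$chain[idx])))
      stop("invalid 'chains': variable assigned to more than one chain")
    if (!is.null(ch$group) && !ch$group %in% names(spec$group_fractions))
      stop("invalid 'chains': unknown group '", ch$group, "'")
    meta$chain[idx] <- ci
  }
  for (bi in seq_along(spec$blocks)) {
    bl <- spec$blocks[[bi]]
    in_layer <- which(meta$layer == bl$layer)
    if (length(in_layer) == 0L)
      stop("invalid 'blocks': unknown layer '", bl$layer, "'")
    free <- in_layer[is.na(meta$block[in_layer]) & is.na(meta$chain[in_layer])]
    if (length(free) < bl$size)
      stop("invalid 'blocks': block size ", bl$size,
           " exceeds free variables in layer '", bl$layer, "'")
    meta$block[free[seq_len(bl$size)]] <- bi
  }
  rownames(meta) <- NULL
  meta
}

#' Generate a synthetic cohort table
#'
#' Latent-Gaussian factor model: within-block variables share a block factor,
#' chain variables follow a first-order autoregressive propagation along the
#' chain, everything else is independent noise. Binary variables threshold
#' the latent at 0; categorical/ordinal variables quantile-bin it into
#' equiprobable levels (codes `1..n_levels`). Whole layers are masked per
#' subject with the layer's missingness probability.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` object: list with `data` (numeric data.frame, `NA` =
#'   missing), `meta` (variable, layer, kind, n_levels), `group` (factor of
#'   diagnostic groups) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- spec$.meta
  n <- spec$n_subjects
  set.seed(spec$seed)

  group <- factor(sample(names(spec$group_fractions), n, replace = TRUE,
                         prob = spec$group_fractions),
                  levels = names(spec$group_fractions))

  p <- nrow(meta)
  lat <- matrix(NA_real_, n, p, dimnames = list(NULL, meta$variable))

  # chain latents first (fixed RNG order: chains, blocks, free variables)
  for (ci in seq_along(spec$chains)) {
    ch <- spec$chains[[ci]]
    s <- ch$strength
    in_grp <- if (is.null(ch$group)) rep(TRUE, n) else group == ch$group
    z_prev <- rnorm(n)
    lat[, ch$variables[1L]] <- z_prev
    for (k in 2L:length(ch$variables)) {
      e <- rnorm(n) * spec$noise_sd
      z <- ifelse(in_grp, s * z_prev + sqrt(1 - s^2) * e, rnorm(n))
      lat[, ch$variables[k]] <- z
      z_prev <- z
    }
  }
  for (bi in seq_along(spec$blocks)) {
    bl <- spec$blocks[[bi]]
    members <- meta$variable[which(!is.na(meta$block) & meta$block == bi)]
    g <- rnorm(n)
    for (v in members)
      lat[, v] <- bl$loading * g + sqrt(1 - bl$loading^2) * rnorm(n) * spec$noise_sd
  }
  for (v in meta$variable[is.na(meta$block) & is.na(meta$chain)])
    lat[, v] <- rnorm(n)

  # transform latents by kind
  dat <- as.data.frame(lat)
  for (j in seq_len(p)) {
    kind <- meta$kind[j]
    if (kind == "binary") {
      dat[[j]] <- as.numeric(lat[, j] > 0)
    } else if (kind %in% c("categorical", "ordinal")) {
      L <- meta$n_levels[j]
      cuts <- c(-Inf, qnorm(seq_len(L - 1L) / L), Inf)
      dat[[j]] <- as.numeric(cut(lat[, j], cuts, labels = FALSE))
    }
  }

  # per-subject, per-layer MCAR masking
  for (ld in spec$layers) {
    pm <- spec$missingness[[ld$name]]
    if (pm > 0) {
      drop <- runif(n) < pm
      dat[drop, meta$layer == ld$name] <- NA
    }
  }

  structure(list(data = dat, meta = meta[, c("variable", "layer", "kind", "n_levels")],
                 group = group, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "subjects x", ncol(x$data), "variables\n")
  cat("Layers:", paste(sprintf("%s (%d)", unique(x$meta$layer),
                               table(x$meta$layer)[unique(x$meta$layer)]),
                       collapse = ", "), "\n")
  cat("Groups:", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Ground truth of a synthetic cohort specification
#'
#' Returns the planted dependencies for use as recovery oracles: consecutive
#' chain pairs (the planted chain edges), all within-block pairs, and the
#' full set of chain-related pairs (including non-consecutive ones, whose
#' dependence decays with chain distance) so null-pair sets can exclude them.
#'
#' @param spec a [cohort_spec()].
#' @return list with `planted_edges` (data.frame var_a, var_b, strength,
#'   source), `chain_pairs_all`, and `chains`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  edges <- list()
  all_chain <- list()
  for (ch in spec$chains) {
    v <- ch$variables
    m <- length(v)
    edges[[length(edges) + 1L]] <- data.frame(
      var_a = v[-m], var_b = v[-1L], strength = ch$strength,
      source = "chain", stringsAsFactors = FALSE)
    cp <- t(combn(v, 2L))
    all_chain[[length(all_chain) + 1L]] <- data.frame(
      var_a = cp[, 1L], var_b = cp[, 2L], stringsAsFactors = FALSE)
  }
  meta <- spec$.meta
  for (bi in seq_along(spec$blocks)) {
    members <- meta$variable[which(!is.na(meta$block) & meta$block == bi)]
    if (length(members) >= 2) {
      bp <- t(combn(members, 2L))
      edges[[length(edges) + 1L]] <- data.frame(
        var_a = bp[, 1L], var_b = bp[, 2L],
        strength = spec$blocks[[bi]]$loading^2, source = "block",
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(edges)) do.call(rbind, edges) else
    data.frame(var_a = character(), var_b = character(),
               strength = numeric(), source = character())
  chain_all <- if (length(all_chain)) do.call(rbind, all_chain) else
    data.frame(var_a = character(), var_b = character())
  list(planted_edges = planted, chain_pairs_all = chain_all,
       chains = spec$chains)
}

#' Write / read a cohort as delimited text
#'
#' The data table is tab-delimited with subjects in rows and variables in
#' columns (empty cell = missing), preceded by a `group` column; the
#' metadata table lists variable, layer, kind and n_levels.
#'
#' @param cohort a `cohort` object.
#' @param data_file,meta_file output paths.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` a
#'   `cohort` object (without the generating spec).
#' @export
write_cohort <- function(cohort, data_file, meta_file) {
  out <- cbind(group = as.character(cohort$group), cohort$data)
  write.table(out, data_file, sep = "\t", quote = FALSE, na = "",
              row.names = FALSE)
  write.table(cohort$meta, meta_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(data_file, meta_file))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(data_file, meta_file) {
  dat <- read.table(data_file, sep = "\t", header = TRUE, na.strings = "",
                    check.names = FALSE)
  meta <- read.table(meta_file, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  group <- factor(dat$group)
  dat$group <- NULL
  if (!identical(sort(names(dat)), sort(meta$variable)))
    stop("data and metadata variable sets differ")
  structure(list(data = dat[, meta$variable, drop = FALSE], meta = meta,
                 group = group, spec = NULL), class = "cohort")
}

#' Read a cohort specification from a YAML config file
#'
#' The config mirrors [cohort_spec()]: top-level `n_subjects`, `seed`,
#' `noise_sd`, `group_fractions` (map), `missingness` (map), `layers`
#' (list of name/n_variables/kinds/n_levels), `blocks` (layer/size/loading)
#' and `chains` (variables/strength/group).
#'
#' @param path YAML file path.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(l)
    layer_def(l$name, l$n_variables,
              kinds = if (is.null(l$kinds)) "continuous" else unlist(l$kinds),
              n_levels = if (is.null(l$n_levels)) 3L else l$n_levels))
  blocks <- lapply(cfg$blocks, function(b) block_def(b$layer, b$size, b$loading))
  chains <- lapply(cfg$chains, function(ch)
    chain_def(unlist(ch$variables), ch$strength, group = ch$group))
  cohort_spec(
    n_subjects = cfg$n_subjects, layers = layers,
    group_fractions = if (is.null(cfg$group_fractions))
      c(control = 622, MCI = 807, AD = 533) / 1962 else unlist(cfg$group_fractions),
    missingness = if (is.null(cfg$missingness)) NULL else unlist(cfg$missingness),
    blocks = blocks, chains = chains,
    noise_sd = if (is.null(cfg$noise_sd)) 1 else cfg$noise_sd,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' A six-layer cohort specification emulating an ADNI-style dataset
#'
#' Desk-scale default conditions: ~60 mixed-type variables over the six
#' layers (genetic, molecular, PET, MRI, risk, phenotype), correlated blocks
#' in the imaging layers, realistic per-layer missingness, group fractions
#' from a typical cohort (622/807/533), and one planted
#' genetic -> PET -> risk -> phenotype chain.
#'
#' @param n_subjects cohort size (default 1000).
#' @param chain_strength loading of the planted chain (default 0.7); set to
#'   `NULL` to omit the chain (fully null ambient structure remains).
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(n_subjects = 1000, chain_strength = 0.7, seed = 1L) {
  layers <- list(
    layer_def("genetic",   8, kinds = c("binary", "categorical", rep("continuous", 6))),
    layer_def("molecular", 10),
    layer_def("PET",       12),
    layer_def("MRI",       12),
    layer_def("risk",      10, kinds = c(rep("binary", 5), "ordinal",
                                         rep("continuous", 4))),
    layer_def("phenotype",  8, kinds = c(rep("continuous", 6), "ordinal", "categorical")))
  blocks <- list(
    block_def("PET", size = 4, loading = 0.85),
    block_def("MRI", size = 5, loading = 0.9),
    block_def("molecular", size = 3, loading = 0.75))
  chains <- if (is.null(chain_strength)) list() else list(
    chain_def(c("genetic_03", "PET_06", "risk_08", "phenotype_01"),
              strength = chain_strength))
  cohort_spec(
    n_subjects = n_subjects, layers = layers,
    missingness = c(genetic = 0.05, molecular = 0.25, PET = 0.2,
                    MRI = 0.15, risk = 0.1, phenotype = 0.05),
    blocks = blocks, chains = chains, seed = seed)
}
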