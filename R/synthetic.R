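# Synthetic ToxCast-like data generator.
#
# Latent mechanism clusters drive everything: each compound carries one
# mechanism of action; assays linked to that mechanism fire with high
# probability while unlinked assays fire at a background rate; fingerprints
# carry mechanism-specific informative bits over a random background; and
# the binary in vivo endpoint is POSITIVE for compounds whose mechanism
# belongs to a designated toxic subset, subject to observation noise. Every
# pipeline stage can therefore be validated against known ground truth
# without any external download.

#' Synthetic dataset configuration
#'
#' @param n_compounds,n_assays matrix dimensions.
#' @param n_mechanisms number of latent mechanisms (>= 1).
#' @param assays_per_mechanism assays linked to each mechanism;
#'   `n_mechanisms * assays_per_mechanism` must not exceed `n_assays`
#'   (remaining assays are background-only).
#' @param p_active_linked probability an assay linked to a compound's
#'   mechanism is active (default 0.9).
#' @param p_active_background activity probability for unlinked assays
#'   (default 0.05).
#' @param flip_noise symmetric call-flip probability applied after the draw.
#' @param missing_rate probability a cell is masked to no-data.
#' @param fp_length fingerprint length in bits.
#' @param fp_informative_bits bits reserved per mechanism, ON for compounds
#'   of that mechanism.
#' @param fp_scaffold_bits leading bits ON for every compound (a shared
#'   scaffold; raises the Tanimoto floor between all pairs).
#' @param fp_background_density Bernoulli rate of the remaining random bits.
#' @param label_mechanisms mechanisms whose compounds are truly toxic.
#' @param label_noise symmetric label-flip probability.
#' @param unknown_rate fraction of compounds whose label is masked UNKNOWN.
#' @param balanced_mechanisms if TRUE, mechanisms are assigned in exactly
#'   equal counts (random order); if FALSE (default) each compound draws its
#'   mechanism i.i.d. uniformly.
#' @param seed master seed; the whole dataset is a deterministic function of
#'   (config, seed).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 100, n_assays = 40,
                             n_mechanisms = 4, assays_per_mechanism = 10,
                             p_active_linked = 0.9,
                             p_active_background = 0.05,
                             flip_noise = 0.05, missing_rate = 0.05,
                             fp_length = 128, fp_informative_bits = 8,
                             fp_scaffold_bits = 0,
                             fp_background_density = 0.1,
                             label_mechanisms = 1:2, label_noise = 0.05,
                             unknown_rate = 0, balanced_mechanisms = FALSE,
                             seed = 1L) {
  probs <- c(p_active_linked, p_active_background, flip_noise, missing_rate,
             fp_background_density, label_noise, unknown_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_mechanisms >= 1,
            n_compounds >= 2, n_assays >= 1,
            all(label_mechanisms %in% seq_len(n_mechanisms)) ||
              length(label_mechanisms) == 0)
  if (n_mechanisms * assays_per_mechanism > n_assays) {
    stop("assays_per_mechanism * n_mechanisms exceeds n_assays", call. = FALSE)
  }
  if (fp_scaffold_bits + n_mechanisms * fp_informative_bits > fp_length) {
    stop("fingerprint bit budget exceeded: scaffold + informative bits per ",
         "mechanism do not fit in fp_length", call. = FALSE)
  }
  structure(list(
    n_compounds = as.integer(n_compounds), n_assays = as.integer(n_assays),
    n_mechanisms = as.integer(n_mechanisms),
    assays_per_mechanism = as.integer(assays_per_mechanism),
    p_active_linked = p_active_linked,
    p_active_background = p_active_background,
    flip_noise = flip_noise, missing_rate = missing_rate,
    fp_length = as.integer(fp_length),
    fp_informative_bits = as.integer(fp_informative_bits),
    fp_scaffold_bits = as.integer(fp_scaffold_bits),
    fp_background_density = fp_background_density,
    label_mechanisms = as.integer(label_mechanisms),
    label_noise = label_noise, unknown_rate = unknown_rate,
    balanced_mechanisms = isTRUE(balanced_mechanisms),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic bioactivity dataset with known ground truth
#'
#' @param config a [synthetic_config()].
#' @return a `babra_dataset` list: `activity` (numeric matrix with `NA` for
#'   masked cells), `fingerprints` (0/1 matrix), `labels` (named
#'   POSITIVE/NEGATIVE/UNKNOWN vector), `trinary` (the pre-imputation
#'   `{1, 0, NA}` view of the same draws), and `truth` (per-compound
#'   mechanism, per-assay linkage, true toxic set, config echo).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_compounds
  p <- config$n_assays
  m <- config$n_mechanisms
  ids <- sprintf("C%0*d", nchar(n), seq_len(n))
  assays <- sprintf("A%0*d", nchar(p), seq_len(p))

  with_seed(config$seed, {
    mech <- if (config$balanced_mechanisms) {
      sample(rep(seq_len(m), length.out = n))
    } else {
      sample.int(m, n, replace = TRUE)
    }
    # assay j is linked to mechanism ceiling(j / apm) for the first m blocks
    assay_mech <- rep(NA_integer_, p)
    for (k in seq_len(m)) {
      assay_mech[((k - 1) * config$assays_per_mechanism + 1):
                 (k * config$assays_per_mechanism)] <- k
    }
    linked <- outer(mech, assay_mech, function(a, b) !is.na(b) & a == b)
    prob <- ifelse(linked, config$p_active_linked, config$p_active_background)
    calls <- matrix(stats::rbinom(n * p, 1, prob), n, p)
    flips <- matrix(stats::rbinom(n * p, 1, config$flip_noise), n, p)
    calls <- abs(calls - flips)
    miss <- matrix(stats::rbinom(n * p, 1, config$missing_rate) == 1, n, p)
    trinary <- calls
    trinary[miss] <- NA_integer_
    storage.mode(trinary) <- "integer"
    dimnames(trinary) <- list(ids, assays)
    activity <- trinary + 0.0

    # fingerprints: [scaffold | m informative blocks | random background]
    L <- config$fp_length
    fp <- matrix(0L, n, L, dimnames = list(ids, NULL))
    if (config$fp_scaffold_bits > 0) fp[, seq_len(config$fp_scaffold_bits)] <- 1L
    ib <- config$fp_informative_bits
    if (ib > 0) {
      for (k in seq_len(m)) {
        cols <- config$fp_scaffold_bits + ((k - 1) * ib + 1):(k * ib)
        fp[mech == k, cols] <- 1L
      }
    }
    bg_start <- config$fp_scaffold_bits + m * ib + 1
    if (bg_start <= L) {
      nb <- L - bg_start + 1
      fp[, bg_start:L] <- matrix(
        stats::rbinom(n * nb, 1, config$fp_background_density), n, nb)
    }

    truly_toxic <- mech %in% config$label_mechanisms
    obs <- truly_toxic
    lflip <- stats::rbinom(n, 1, config$label_noise) == 1
    obs[lflip] <- !obs[lflip]
    labels <- stats::setNames(ifelse(obs, "POSITIVE", "NEGATIVE"), ids)
    if (config$unknown_rate > 0) {
      labels[stats::rbinom(n, 1, config$unknown_rate) == 1] <- "UNKNOWN"
    }

    structure(list(
      activity = activity,
      fingerprints = fp,
      labels = labels,
      trinary = trinary,
      truth = list(mechanism = stats::setNames(mech, ids),
                   assay_mechanism = stats::setNames(assay_mech, assays),
                   toxic = ids[truly_toxic],
                   config = unclass(config))
    ), class = "babra_dataset")
  })
}

SYNTHETIC_PRESETS <- list(
  # strong mechanism-to-endpoint signal at ToxCast-like scale
  signal = list(n_compounds = 200, n_assays = 40, n_mechanisms = 4,
                assays_per_mechanism = 10, p_active_linked = 0.9,
                p_active_background = 0.05, flip_noise = 0.05,
                missing_rate = 0.05, fp_length = 128,
                fp_informative_bits = 8, fp_background_density = 0.1,
                label_mechanisms = 1:2, label_noise = 0.05),
  # endpoint independent of every feature: labels are a fair coin
  null = list(n_compounds = 200, n_assays = 40, n_mechanisms = 4,
              assays_per_mechanism = 10, p_active_linked = 0.9,
              p_active_background = 0.05, flip_noise = 0.05,
              missing_rate = 0.05, fp_length = 128,
              fp_informative_bits = 8, fp_background_density = 0.1,
              label_mechanisms = integer(0), label_noise = 0.5),
  # two well-separated bioactivity clusters, noiseless labels
  `two-cluster` = list(n_compounds = 60, n_assays = 20, n_mechanisms = 2,
                       assays_per_mechanism = 10, p_active_linked = 0.9,
                       p_active_background = 0.05, flip_noise = 0.05,
                       missing_rate = 0, fp_length = 64,
                       fp_informative_bits = 8, fp_background_density = 0.1,
                       label_mechanisms = 1, label_noise = 0),
  # near-identical structures across mechanisms while bioactivity differs:
  # a shared 96-bit scaffold plus dense uninformative background bits makes
  # Tanimoto similarity blind to the mechanism that drives the endpoint
  `activity-cliff` = list(n_compounds = 120, n_assays = 40, n_mechanisms = 4,
                          assays_per_mechanism = 10, p_active_linked = 0.9,
                          p_active_background = 0.05, flip_noise = 0.05,
                          missing_rate = 0.05, fp_length = 128,
                          fp_informative_bits = 0, fp_scaffold_bits = 96,
                          fp_background_density = 0.5,
                          label_mechanisms = 1:2, label_noise = 0.05)
)

#' Frozen synthetic-data presets
#'
#' Named configurations exercising distinct regimes: `"signal"` (endpoint
#' driven by assay mechanisms), `"null"` (endpoint independent of all
#' features), `"two-cluster"` (two clean bioactivity clusters) and
#' `"activity-cliff"` (structures nearly identical across mechanisms while
#' bioactivity and toxicity differ — the failure mode of structure-only
#' read-across).
#'
#' @param name preset name.
#' @param seed master seed installed into the returned config.
#' @return a [synthetic_config()].
#' @export
preset <- function(name, seed = 1L) {
  if (!name %in% names(SYNTHETIC_PRESETS)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(SYNTHETIC_PRESETS), collapse = ", ")),
         call. = FALSE)
  }
  do.call(synthetic_config, c(SYNTHETIC_PRESETS[[name]], list(seed = seed)))
}
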