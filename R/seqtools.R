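# Residue-level scales used by the sequence descriptors.
# Chou-Fasman alpha-helix propensities (P_alpha; higher = stronger former).
CHOU_FASMAN_ALPHA <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)

# Kyte-Doolittle hydropathy, normalized to [0, 1] as (kd + 4.5) / 9.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

residue_charges <- function(residues) {
  ifelse(residues %in% c("K", "R"), 1L,
         ifelse(residues %in% c("D", "E"), -1L, 0L))
}

# delta_max depends only on (n+, n-, n0, g); cache it so scanning large
# scramble pools (identical composition) pays the construction cost once.
.delta_max_cache <- new.env(parent = emptyenv())

delta_max_cached <- function(npos, nneg, nneu, g) {
  key <- paste(npos, nneg, nneu, g, sep = "_")
  val <- .delta_max_cache[[key]]
  if (is.null(val)) {
    val <- delta_max_cpp(npos, nneg, nneu, g)
    .delta_max_cache[[key]] <- val
  }
  val
}

#' Charge-patterning descriptor (kappa) of a protein sequence
#'
#' Computes the standard charge-composition quantities (fractions of
#' positive and negative residues, FCR, NCPR, sigma) and the patterning
#' parameter kappa: for each blob size `g`, the window charge asymmetry
#' `sigma_i = NCPR_i^2 / FCR_i` is evaluated on every length-`g` window,
#' `delta_g` is the mean squared deviation of `sigma_i` from the global
#' sigma, and `kappa` is the mean over blob sizes of `delta_g / delta_max_g`.
#' Lysine and arginine count +1, aspartate and glutamate -1; histidine and
#' termini are treated as neutral. `delta_max_g` comes from a deterministic
#' maximally-segregated construction: the maximum of `delta_g` over all
#' arrangements that keep each charge type in at most two blocks with the
#' neutral residues distributed around them — a family that reproduces
#' exhaustive-enumeration maxima exactly on short sequences.
#'
#' @param sequence Amino-acid string (20-letter alphabet).
#' @param blob_sizes Window sizes for the blob decomposition.
#'
#' @return A one-row tibble with `f_plus`, `f_minus`, `fcr`, `ncpr`,
#'   `sigma`, per-blob `delta`/`delta_max`, and `kappa`.
#' @export
charge_pattern_kappa <- function(sequence, blob_sizes = c(5, 6)) {
  residues <- assert_protein_sequence(sequence)
  n <- length(residues)
  if (n < max(blob_sizes)) {
    abort(sprintf("sequence length %d is shorter than the largest blob size %d.",
                  n, max(blob_sizes)),
          class = "osmofret_length_error")
  }
  ch <- residue_charges(residues)
  f_plus <- mean(ch == 1); f_minus <- mean(ch == -1)
  fcr <- f_plus + f_minus; ncpr <- f_plus - f_minus
  if (fcr == 0) {
    abort("sequence has no charged residues; kappa is undefined.",
          class = "osmofret_undefined_kappa")
  }
  npos <- sum(ch == 1); nneg <- sum(ch == -1); nneu <- n - npos - nneg
  deltas <- vapply(blob_sizes, function(g) delta_blob_cpp(ch, g), 0)
  dmaxes <- vapply(blob_sizes, function(g) delta_max_cached(npos, nneg, nneu, g), 0)
  out <- tibble(
    f_plus = f_plus, f_minus = f_minus, fcr = fcr, ncpr = ncpr,
    sigma = ncpr^2 / fcr,
    kappa = mean(deltas / dmaxes)
  )
  out$delta <- list(setNames(deltas, paste0("g", blob_sizes)))
  out$delta_max <- list(setNames(dmaxes, paste0("g", blob_sizes)))
  out
}

#' Sliding-window helix-propensity score
#'
#' Window means of the shipped Chou-Fasman alpha-helix propensity scale
#' (`P_alpha`), a ranking proxy for per-sequence helix-forming tendency.
#' Scores are comparable between sequences of identical composition, where
#' differences reflect residue arrangement only.
#'
#' @param sequence Amino-acid string.
#' @param window Window length (default 6, roughly 1.5 helix turns).
#'
#' @return A list with `profile` (tibble of window start positions and
#'   scores), `mean_score` (mean over windows) and `max_score`.
#' @export
helix_propensity_score <- function(sequence, window = 6) {
  residues <- assert_protein_sequence(sequence)
  window <- assert_count(window, "window", lower = 1L)
  n <- length(residues)
  if (window > n) {
    abort(sprintf("window %d exceeds the sequence length %d.", window, n),
          class = "osmofret_length_error")
  }
  per_res <- unname(CHOU_FASMAN_ALPHA[residues])
  cs <- cumsum(c(0, per_res))
  scores <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  list(
    profile = tibble(position = seq_len(n - window + 1L), score = scores),
    mean_score = mean(scores),
    max_score = max(scores)
  )
}

#' Charge-hydropathy disorder proxy
#'
#' Places a sequence on the charge-hydropathy plane: mean absolute net
#' charge per residue versus mean Kyte-Doolittle hydropathy normalized to
#' `[0, 1]`. Sequences below the boundary line
#' `H = (R + 1.151) / 2.785` are flagged as disordered. Both coordinates
#' are composition-only, hence invariant under permutation.
#'
#' @param sequence Amino-acid string.
#'
#' @return A one-row tibble with `mean_net_charge`, `mean_hydropathy` and
#'   `disordered`.
#' @export
disorder_proxy <- function(sequence) {
  residues <- assert_protein_sequence(sequence)
  r <- abs(mean(residue_charges(residues)))
  h <- mean((unname(KYTE_DOOLITTLE[residues]) + 4.5) / 9)
  tibble(mean_net_charge = r, mean_hydropathy = h,
         disordered = h < (r + 1.151) / 2.785)
}

#' Select charge-segregated, helix-poor scrambles
#'
#' Filters a pool of composition-preserving scrambles against a reference
#' sequence, keeping candidates that (i) have strictly larger kappa (less
#' charge mixing), (ii) have a strictly lower mean helix-propensity score,
#' and (iii) preserve the reference's disorder flag. Survivors are ranked
#' by kappa (descending) and the top `n_keep` returned; if fewer survive, a
#' warning is raised and all survivors returned.
#'
#' @param reference Reference amino-acid string.
#' @param pool Character vector of candidate scrambles (identical
#'   composition, e.g. from [gen_scramble_pool()]).
#' @param n_keep Number of scrambles to keep.
#' @param blob_sizes Blob sizes for kappa.
#' @param helix_window Window for the helix score.
#'
#' @return A list of class `scramble_selection`: `reference` (one-row
#'   tibble of descriptors), `candidates` (tibble of all pool descriptors
#'   with a `selected` flag), and `selected` (the kept sequences, ranked).
#' @export
select_scrambles <- function(reference, pool, n_keep = 5,
                             blob_sizes = c(5, 6), helix_window = 6) {
  ref_res <- assert_protein_sequence(reference)
  n_keep <- assert_count(n_keep, "n_keep", lower = 1L)
  ref_kappa <- charge_pattern_kappa(reference, blob_sizes)$kappa
  ref_helix <- helix_propensity_score(reference, helix_window)$mean_score
  ref_dis <- disorder_proxy(reference)$disordered

  ref_sorted <- sort(ref_res)
  per_res <- unname(CHOU_FASMAN_ALPHA)
  names(per_res) <- names(CHOU_FASMAN_ALPHA)
  ch_ref <- residue_charges(ref_res)
  npos <- sum(ch_ref == 1); nneg <- sum(ch_ref == -1)
  nneu <- length(ch_ref) - npos - nneg
  dmax <- vapply(blob_sizes,
                 function(g) delta_max_cached(npos, nneg, nneu, g), 0)
  n <- length(ref_res)
  stats <- vapply(pool, function(s) {
    res <- assert_protein_sequence(s)
    if (!identical(sort(res), ref_sorted)) {
      abort("pool contains a sequence whose composition differs from the reference.",
            class = "osmofret_invalid_parameter")
    }
    ch <- residue_charges(res)
    kappa <- mean(vapply(seq_along(blob_sizes),
                         function(i) delta_blob_cpp(ch, blob_sizes[i]) / dmax[i], 0))
    cs <- cumsum(c(0, per_res[res]))
    helix <- mean((cs[(helix_window + 1):(n + 1)] -
                     cs[1:(n - helix_window + 1)]) / helix_window)
    c(kappa, helix)
  }, c(0, 0))
  # disorder is composition-only, hence identical across a true scramble pool
  cand <- tibble(
    sequence = pool,
    kappa = stats[1, ],
    helix_score = stats[2, ],
    disordered = ref_dis
  )
  cand <- dplyr::mutate(cand,
    selected = .data$kappa > ref_kappa & .data$helix_score < ref_helix &
      .data$disordered == ref_dis)
  survivors <- cand |>
    dplyr::filter(.data$selected) |>
    dplyr::arrange(dplyr::desc(.data$kappa))
  if (nrow(survivors) < n_keep) {
    warn(sprintf("only %d of the requested %d scrambles survive the criteria.",
                 nrow(survivors), n_keep))
  }
  kept <- utils::head(survivors, n_keep)
  structure(
    list(
      reference = tibble(sequence = reference, kappa = ref_kappa,
                         helix_score = ref_helix, disordered = ref_dis),
      candidates = cand,
      selected = kept
    ),
    class = "scramble_selection"
  )
}

#' @export
print.scramble_selection <- function(x, ...) {
  cat(sprintf("<scramble_selection> %d/%d candidates kept (reference kappa %.3f)\n",
              nrow(x$selected), nrow(x$candidates), x$reference$kappa))
  invisible(x)
}

#' Composition-preserving scramble pool
#'
#' Draws `n` independent uniform permutations of the input sequence
#' (Fisher-Yates, via [sample()]), each therefore sharing its exact residue
#' multiset and length. Deterministic given `seed`.
#'
#' @param sequence Amino-acid string (length >= 2, standard alphabet).
#' @param n Number of scrambles.
#' @param seed Integer seed.
#'
#' @return Character vector of `n` scrambled sequences.
#' @export
gen_scramble_pool <- function(sequence, n, seed = 1L) {
  residues <- assert_protein_sequence(sequence)
  n <- assert_count(n, "n", lower = 1L)
  with_local_seed(seed, {
    vapply(seq_len(n),
           function(i) paste(sample(residues), collapse = ""),
           character(1))
  })
}
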