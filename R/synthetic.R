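# Synthetic peptide populations with planted labels, the test bed for the
# control experiments.

#' Specification of a synthetic peptide dataset
#'
#' Describes a population of random 20-letter peptide sequences with labels
#' planted by one of three rules: `composition_threshold` (positive iff the
#' fraction of designated letters exceeds a cutoff), `motif` (positive iff any
#' listed motif occurs as a contiguous substring) or `size_regression`
#' (target = sum of monoisotopic residue masses, a deterministic size proxy).
#'
#' @param n Number of sequences.
#' @param length_range Integer `(min, max)` residue counts, `min >= 3`;
#'   lengths are drawn uniformly.
#' @param composition Optional named per-letter sampling weights (default
#'   uniform over the 20 canonical letters).
#' @param label_rule `"composition_threshold"`, `"motif"` or
#'   `"size_regression"`.
#' @param letters Designated letters for the composition rule.
#' @param cutoff Composition fraction cutoff.
#' @param motifs Non-empty motif list for the motif rule.
#' @param noise Label-flip probability in `[0, 0.5)` (binary rules only).
#' @param imbalance Optional target positive fraction, achieved by rejection
#'   sampling (binary rules only; `NULL` keeps the natural rate).
#' @param seed Integer seed; a fixed spec and seed always generate the same
#'   dataset.
#' @return A `synthetic_spec` list.
#' @export
#' @examples
#' spec <- synthetic_spec(n = 50, label_rule = "motif", seed = 1)
synthetic_spec <- function(n = 2000L, length_range = c(10L, 50L),
                           composition = NULL,
                           label_rule = c("composition_threshold", "motif",
                                          "size_regression"),
                           letters = c("K", "R"), cutoff = 0.15,
                           motifs = c("KKK", "RRR"), noise = 0,
                           imbalance = NULL, seed = 1L) {
  label_rule <- match.arg(label_rule)
  n <- as.integer(n)
  length_range <- as.integer(length_range)
  if (is.na(n) || n < 1) pep_abort("n must be positive", "pep_config_error")
  if (length(length_range) != 2 || length_range[1] < 3 ||
      length_range[2] < length_range[1]) {
    pep_abort("length_range must be (min, max) with min >= 3",
              "pep_config_error")
  }
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (!all(names(composition) %in% AA_ALPHABET) || any(composition < 0) ||
      sum(composition) <= 0) {
    pep_abort("composition must be non-negative weights over canonical letters",
              "pep_config_error")
  }
  if (label_rule == "motif") {
    if (length(motifs) == 0) {
      pep_abort("motif list must be non-empty", "pep_config_error")
    }
    motifs <- validate_sequences(motifs, what = "motif")
  }
  if (label_rule == "composition_threshold") {
    letters <- toupper(letters)
    if (!all(letters %in% AA_ALPHABET) || length(letters) == 0) {
      pep_abort("letters must be canonical amino-acid codes",
                "pep_config_error")
    }
  }
  if (noise < 0 || noise >= 0.5) {
    pep_abort("noise must be in [0, 0.5)", "pep_config_error")
  }
  if (!is.null(imbalance)) {
    if (label_rule == "size_regression") {
      pep_abort("imbalance only applies to binary label rules",
                "pep_config_error")
    }
    if (imbalance <= 0 || imbalance >= 1) {
      pep_abort("imbalance must be in (0, 1)", "pep_config_error")
    }
  }
  structure(list(n = n, length_range = length_range,
                 composition = composition[order(names(composition))],
                 label_rule = label_rule, letters = letters, cutoff = cutoff,
                 motifs = motifs, noise = noise, imbalance = imbalance,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec: n=%d, lengths %d-%d, rule %s, seed %d>\n",
              x$n, x$length_range[1], x$length_range[2], x$label_rule,
              x$seed))
  invisible(x)
}

# label rules, also used by the brute-force relabeling test
label_composition <- function(seqs, letters, cutoff) {
  frac <- vapply(strsplit(seqs, ""), function(ch) mean(ch %in% letters),
                 numeric(1))
  as.integer(frac > cutoff)
}

label_motif <- function(seqs, motifs) {
  hit <- rep(FALSE, length(seqs))
  for (m in motifs) hit <- hit | grepl(m, seqs, fixed = TRUE)
  as.integer(hit)
}

label_size <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) sum(RESIDUE_MASSES[ch]), numeric(1))
}

#' Apply a spec's label rule to sequences
#'
#' @param spec A [synthetic_spec()].
#' @param seqs Character vector of sequences.
#' @return Numeric label vector (0/1 for binary rules, mass sum for
#'   regression), without noise.
#' @export
apply_label_rule <- function(spec, seqs) {
  switch(spec$label_rule,
    composition_threshold = label_composition(seqs, spec$letters, spec$cutoff),
    motif = label_motif(seqs, spec$motifs),
    size_regression = label_size(seqs))
}

draw_sequences <- function(k, spec) {
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), k,
                 replace = TRUE)
  letters_pool <- names(spec$composition)
  vapply(lens, function(L) {
    paste(sample(letters_pool, L, replace = TRUE, prob = spec$composition),
          collapse = "")
  }, character(1))
}

#' Generate a labeled synthetic peptide dataset
#'
#' Draws sequences according to the spec's composition and length range and
#' labels them with the planted rule.  A target positive fraction is achieved
#' by rejection sampling (capped; a generator error is raised if the target
#' rate is unreachable); label noise then flips the stated fraction of binary
#' labels.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `id`, `sequence`, `label`.
#' @export
#' @examples
#' head(generate_peptides(synthetic_spec(n = 20, seed = 7)))
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_peptides_impl(spec))
}

generate_peptides_impl <- function(spec) {
  if (is.null(spec$imbalance)) {
    seqs <- draw_sequences(spec$n, spec)
    labels <- apply_label_rule(spec, seqs)
  } else {
    n_pos_target <- round(spec$n * spec$imbalance)
    n_neg_target <- spec$n - n_pos_target
    pos <- character(0)
    neg <- character(0)
    attempts <- 0L
    max_attempts <- 5000L * spec$n
    batch <- max(spec$n, 1000L)
    while ((length(pos) < n_pos_target || length(neg) < n_neg_target) &&
           attempts < max_attempts) {
      s <- draw_sequences(batch, spec)
      attempts <- attempts + batch
      lab <- apply_label_rule(spec, s)
      pos <- c(pos, s[lab == 1])[seq_len(min(n_pos_target,
                                             length(pos) + sum(lab == 1)))]
      neg <- c(neg, s[lab == 0])[seq_len(min(n_neg_target,
                                             length(neg) + sum(lab == 0)))]
    }
    if (length(pos) < n_pos_target || length(neg) < n_neg_target) {
      pep_abort(sprintf(
        "generator error: target imbalance %.3f unreachable after %d draws",
        spec$imbalance, attempts), "pep_config_error")
    }
    # interleave deterministically, then shuffle row order
    seqs <- c(pos, neg)
    labels <- c(rep(1L, n_pos_target), rep(0L, n_neg_target))
    ord <- sample(length(seqs))
    seqs <- seqs[ord]
    labels <- labels[ord]
  }
  if (spec$noise > 0 && spec$label_rule != "size_regression") {
    flip <- runif(spec$n) < spec$noise
    labels[flip] <- 1L - labels[flip]
  }
  tibble(id = paste0("pep", seq_len(spec$n)), sequence = seqs, label = labels)
}
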