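.FEATURE_DEFAULTS <- list(
  F1  = list(group = "spectrum", k = 1L),
  F2  = list(group = "spectrum", k = 2L),
  F3  = list(group = "spectrum", k = 3L),
  F4  = list(group = "spectrum", k = 4L),
  F5  = list(group = "spectrum", k = 5L),
  F6  = list(group = "mismatch", k = 3L, m = 1L),
  F7  = list(group = "mismatch", k = 4L, m = 1L),
  F8  = list(group = "mismatch", k = 5L, m = 1L),
  F9  = list(group = "revckmer", k = 1L),
  F10 = list(group = "revckmer", k = 2L),
  F11 = list(group = "revckmer", k = 3L),
  F12 = list(group = "revckmer", k = 4L),
  F13 = list(group = "revckmer", k = 5L),
  F14 = list(group = "psenc", variant = "PCPseDNC", lambda = 9L,  w = 0.05),
  F15 = list(group = "psenc", variant = "PCPseTNC", lambda = 1L,  w = 0.05),
  F16 = list(group = "psenc", variant = "SCPseDNC", lambda = 15L, w = 0.05),
  F17 = list(group = "psenc", variant = "SCPseTNC", lambda = 1L,  w = 0.05)
)

#' Feature specification F1-F17
#'
#' Declarative description of one of the seventeen sequence-derived
#' features. Defaults follow the reference configuration: spectrum profiles
#' k = 1..5 (F1-F5); (k,1)-mismatch profiles for k = 3,4,5 (F6-F8);
#' RevcKmer k = 1..5 (F9-F13); pseudo nucleotide composition with
#' lambda = 9 (PCPseDNC, F14), 1 (PCPseTNC, F15), 15 (SCPseDNC, F16),
#' 1 (SCPseTNC, F17), all with weight `w = 0.05`.
#'
#' @param index feature index, `"F1"` .. `"F17"`.
#' @param ... overrides of the defaults (`k`, `m`, `lambda`, `w`).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(index, ...) {
  if (!index %in% names(.FEATURE_DEFAULTS)) {
    stop(sprintf("unknown feature index '%s' (expected F1..F17)", index))
  }
  spec <- utils::modifyList(.FEATURE_DEFAULTS[[index]], list(...))
  spec$index <- index
  if (spec$group %in% c("spectrum", "mismatch", "revckmer") && spec$k < 1L) {
    stop("k must be >= 1")
  }
  if (spec$group == "mismatch" && (spec$m < 0L || spec$m >= spec$k)) {
    stop(sprintf("mismatch spec needs 0 <= m < k (got k=%d, m=%d)", spec$k, spec$m))
  }
  if (spec$group == "psenc") {
    if (spec$lambda < 1L) stop("lambda must be >= 1")
    if (spec$w <= 0) stop("w must be > 0")
  }
  structure(spec, class = "feature_spec")
}

#' All seventeen default feature specs
#'
#' @return named list of [feature_spec()] objects F1..F17.
#' @export
all_feature_specs <- function() {
  setNames(lapply(names(.FEATURE_DEFAULTS), feature_spec),
           names(.FEATURE_DEFAULTS))
}

#' Closed-form dimension of a feature spec
#'
#' Spectrum/mismatch: `4^k`; RevcKmer: `4^k/2` (odd k) or
#' `(4^k + 4^(k/2))/2` (even k); parallel pseudo-composition:
#' `base + lambda`; series: `base + N_p * lambda` with `N_p` the number of
#' properties (6 for di-, 12 for tri-nucleotides by default).
#'
#' @param spec a [feature_spec()].
#' @param props optional [property_table()] (sets `N_p` for series variants).
#' @return integer dimension.
#' @export
feature_dim <- function(spec, props = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  switch(spec$group,
    spectrum = 4L^spec$k,
    mismatch = 4L^spec$k,
    revckmer = if (spec$k %% 2L == 1L) 4L^spec$k / 2L
               else (4L^spec$k + 4L^(spec$k %/% 2L)) / 2L,
    psenc = {
      di <- endsWith(spec$variant, "DNC")
      base <- if (di) 16L else 64L
      if (startsWith(spec$variant, "PC")) base + spec$lambda
      else {
        np <- if (!is.null(props)) ncol(props$values) else if (di) 6L else 12L
        base + np * spec$lambda
      }
    })
}

#' @export
print.feature_spec <- function(x, ...) {
  par <- switch(x$group,
    spectrum = sprintf("k=%d", x$k),
    mismatch = sprintf("k=%d, m=%d", x$k, x$m),
    revckmer = sprintf("k=%d", x$k),
    psenc = sprintf("%s, lambda=%d, w=%g", x$variant, x$lambda, x$w))
  cat(sprintf("<feature_spec> %s [%s: %s], dim %d\n",
              x$index, x$group, par, feature_dim(x)))
  invisible(x)
}

#' Encode one sequence under a feature spec
#'
#' Dispatches to [spectrum_profile()], [mismatch_profile()],
#' [revc_kmer_profile()] or [pse_nc()] according to the spec.
#'
#' @param seq a single DNA sequence.
#' @param spec a [feature_spec()] (or an index string like `"F6"`).
#' @param props optional [property_table()] for pseudo-composition specs.
#' @return named numeric feature vector.
#' @export
encode <- function(seq, spec, props = NULL) {
  drop_row(encode_matrix(seq, spec, props))
}

#' Encode many sequences into a feature matrix
#'
#' @param seqs named character vector of sequences.
#' @param spec a [feature_spec()] or index string.
#' @param props optional [property_table()].
#' @return numeric matrix, rows = sequences, columns = feature components
#'   prefixed with the feature index (e.g. `F3.AAA`).
#' @export
encode_matrix <- function(seqs, spec, props = NULL) {
  if (is.character(spec)) spec <- feature_spec(spec)
  stopifnot(inherits(spec, "feature_spec"))
  m <- switch(spec$group,
    spectrum = spectrum_matrix(seqs, spec$k),
    mismatch = mismatch_matrix(seqs, spec$k, spec$m),
    revckmer = revckmer_matrix(seqs, spec$k),
    psenc = psenc_matrix(seqs, spec$variant, spec$lambda, spec$w, props))
  colnames(m) <- paste0(spec$index, ".", colnames(m))
  m
}

.FEATURE_GROUPS <- list(
  SP  = paste0("F", 1:5),
  MP  = paste0("F", 6:8),
  RCK = paste0("F", 9:13),
  PNC = paste0("F", 14:17)
)

#' Feature-group membership
#'
#' The four groups feeding the neural ensemble: `SP` (spectrum, F1-F5),
#' `MP` (mismatch, F6-F8), `RCK` (RevcKmer, F9-F13), `PNC`
#' (pseudo nucleotide composition, F14-F17).
#'
#' @return named list of feature-index vectors.
#' @export
feature_groups <- function() .FEATURE_GROUPS

#' Concatenated group feature matrix
#'
#' Concatenates the group's encoders in F-index order. With the default
#' specs the dimensions are SP = 1364, MP = 1344, RCK = 692, PNC = 272.
#'
#' @param seqs named character vector of sequences.
#' @param group one of `"SP"`, `"MP"`, `"RCK"`, `"PNC"`.
#' @param props optional [property_table()] pair as a list with elements
#'   `di` and `tri` (defaults used otherwise).
#' @return numeric matrix, rows = sequences.
#' @export
group_matrix <- function(seqs, group, props = NULL) {
  if (!group %in% names(.FEATURE_GROUPS)) {
    stop(sprintf("unknown feature group '%s' (expected SP, MP, RCK or PNC)", group))
  }
  specs <- lapply(.FEATURE_GROUPS[[group]], feature_spec)
  do.call(cbind, lapply(specs, function(sp) {
    encode_matrix(seqs, sp, props = pick_props(sp, props))
  }))
}

pick_props <- function(spec, props) {
  if (spec$group != "psenc" || is.null(props)) return(NULL)
  if (inherits(props, "property_table")) return(props)
  props[[if (endsWith(spec$variant, "DNC")) "di" else "tri"]]
}

#' Concatenated group feature vector for one sequence
#'
#' @inheritParams group_matrix
#' @param seq a single DNA sequence.
#' @return named numeric vector.
#' @export
group_concat <- function(seq, group, props = NULL) {
  drop_row(group_matrix(seq, group, props))
}
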