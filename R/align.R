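# Global percent identity and the length-dependent identity threshold.
#
# Identity metric: Needleman-Wunsch global alignment with BLOSUM62 and
# affine gaps (opening 11, extension 1 per gapped position, Biostrings
# convention: a length-k gap costs 11 + k). Identity is counted over all
# alignment columns except those in terminal (overhang) gap runs, so a
# fragment aligned inside a full-length protein is judged only on the
# region it covers. The pair is aligned in a canonical orientation
# (lexicographically smaller residue string as pattern) so the statistic
# is exactly symmetric even when co-optimal tracebacks differ.

.GAP_OPEN <- 11
.GAP_EXT <- 1

# U (Sec) and O (Pyl) are absent from BLOSUM62; scored as X. Records keep
# the original letters.
.score_residues <- function(x) chartr("UO", "XX", x)

.identity_from_aligned <- function(p, s) {
  n <- nchar(p)
  if (n == 0L) return(c(identity_pct = 0, aligned_cols = 0))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  ident <- sum(pc == sc & pc != "-")
  c(identity_pct = 100 * ident / n, aligned_cols = n)
}

#' Percent identity of one reference against many candidates
#'
#' Vectorized form of [global_identity()]: one global alignment per
#' candidate against the same reference, identical in result to calling
#' `global_identity` pairwise.
#'
#' @param ref a residue string (or single record row).
#' @param candidates character vector of residue strings.
#' @return `data.frame` with columns `identity_pct` and `aligned_cols`,
#'   one row per candidate.
#' @export
pair_identities <- function(ref, candidates) {
  ref <- .as_residues(ref)
  candidates <- vapply(candidates, .as_residues, character(1),
                       USE.NAMES = FALSE)
  if (!nzchar(ref) || any(!nzchar(candidates))) {
    stop("empty sequence", call. = FALSE)
  }
  refm <- .score_residues(ref)
  candm <- .score_residues(candidates)
  out <- matrix(0, nrow = length(candm), ncol = 2,
                dimnames = list(NULL, c("identity_pct", "aligned_cols")))
  # canonical orientation: smaller string is the pattern
  grpA <- which(candm <= refm)
  grpB <- which(candm > refm)
  if (length(grpA)) {
    aln <- pairwiseAlignment(AAStringSet(candm[grpA]), AAString(refm),
                             substitutionMatrix = "BLOSUM62",
                             gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT,
                             type = "global")
    p <- as.character(pattern(aln))
    s <- as.character(subject(aln))
    for (k in seq_along(grpA)) {
      out[grpA[k], ] <- .identity_from_aligned(p[k], s[k])
    }
  }
  for (k in grpB) {
    aln <- pairwiseAlignment(AAString(refm), AAString(candm[k]),
                             substitutionMatrix = "BLOSUM62",
                             gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT,
                             type = "global")
    out[k, ] <- .identity_from_aligned(as.character(pattern(aln)),
                                       as.character(subject(aln)))
  }
  as.data.frame(out)
}

.as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "residues" %in% names(x))
    return(x$residues)
  }
  as.character(x)
}

#' Global percent identity of a sequence pair
#'
#' @param a,b residue strings (or single record rows).
#' @return list with `identity_pct` (0-100) and `aligned_cols` (alignment
#'   columns outside terminal gap runs; the `L` fed to the Rost curve).
#' @examples
#' global_identity("MKVLLT", "MKVALT")$identity_pct  # 5/6 = 83.33
#' @export
global_identity <- function(a, b) {
  st <- pair_identities(a, .as_residues(b))
  list(identity_pct = st$identity_pct[1], aligned_cols = st$aligned_cols[1])
}

#' Identity-threshold policy
#'
#' Bundles the user cutoff with the parameters of the length-dependent
#' floor. `user_cutoff_pct` defaults to 53, the fixed component of the
#' default threshold. The curve constants (scale 480, base exponent -0.32,
#' decay length 1000) define the twilight-zone curve; `rost_offset_n`
#' shifts the whole curve (0 = the curve itself) and is exposed because
#' the curve is conventionally published as a family indexed by such an
#' offset.
#'
#' @param user_cutoff_pct identity cutoff in percent, within [0, 100].
#' @param rost_offset_n additive offset on the curve, default 0.
#' @return a `threshold_policy` list.
#' @export
threshold_policy <- function(user_cutoff_pct = 53, rost_offset_n = 0) {
  user_cutoff_pct <- as.numeric(user_cutoff_pct)
  if (length(user_cutoff_pct) != 1L || is.na(user_cutoff_pct) ||
      user_cutoff_pct < 0 || user_cutoff_pct > 100) {
    stop("user_cutoff_pct must be a single value in [0, 100]", call. = FALSE)
  }
  structure(list(user_cutoff_pct = user_cutoff_pct,
                 rost_offset_n = as.numeric(rost_offset_n),
                 rost_scale = 480, rost_base_exp = -0.32,
                 rost_decay = 1000),
            class = "threshold_policy")
}

#' Length-dependent minimum identity (Rost curve)
#'
#' `n + 480 * L^(-0.32 * (1 + exp(-L/1000)))`, clamped to [0, 100]:
#' short alignments demand high identity before homology can be called,
#' long alignments relax towards the ~19-20% twilight-zone asymptote.
#'
#' @param L integer vector of alignment lengths (columns), all >= 1.
#' @param policy a [threshold_policy()].
#' @return threshold(s) in percent.
#' @export
rost_threshold <- function(L, policy = threshold_policy()) {
  L <- as.numeric(L)
  if (length(L) == 0L || any(is.na(L)) || any(L < 1)) {
    stop("L must be >= 1", call. = FALSE)
  }
  v <- policy$rost_offset_n +
    policy$rost_scale * L^(policy$rost_base_exp * (1 + exp(-L / policy$rost_decay)))
  pmin(100, pmax(0, v))
}

#' Effective clustering threshold
#'
#' The larger of the user cutoff and the Rost curve at length `L`; the
#' curve is a floor the user cutoff can never undercut.
#'
#' @inheritParams rost_threshold
#' @return threshold(s) in percent.
#' @export
effective_threshold <- function(L, policy = threshold_policy()) {
  pmax(policy$user_cutoff_pct, rost_threshold(L, policy))
}
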