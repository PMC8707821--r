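#' Default physicochemical amino-acid grouping
#'
#' Partition of the 20 standard residues into physicochemical classes used
#' by the group-conservation scheme: aliphatic, aromatic, polar, basic,
#' acidic and special (the conformationally special glycine and proline).
#' Every residue belongs to exactly one group. The partition is
#' configurable because conservation at the group level depends on it;
#' identity-level results do not.
#'
#' @return Named list of character vectors of one-letter codes.
#' @export
default_group_scheme <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M", "C"),
    aromatic = c("F", "W", "Y"),
    polar = c("S", "T", "N", "Q"),
    basic = c("K", "R", "H"),
    acidic = c("D", "E"),
    special = c("G", "P")
  )
}

.validate_scheme <- function(scheme) {
  all20 <- sort(unlist(scheme, use.names = FALSE))
  if (any(duplicated(all20))) {
    stop("group scheme assigns a residue to more than one group", call. = FALSE)
  }
  invisible(scheme)
}

#' Conservation score of a residue pair
#'
#' Scores an aligned residue pair: 1.0 for identical residues, 0.5 for
#' different residues from the same physicochemical group, 0 otherwise.
#' Gaps carry no conserved residue and score 0 against anything, including
#' another gap.
#'
#' @param a,b one-letter residue codes (or `"-"` for a gap).
#' @param scheme group scheme, see [default_group_scheme()].
#' @return 1.0, 0.5 or 0.
#' @export
pair_score <- function(a, b, scheme = default_group_scheme()) {
  a <- toupper(a); b <- toupper(b)
  gap <- c("-", ".")
  known <- c(unlist(scheme, use.names = FALSE), gap)
  if (!(a %in% known) || !(b %in% known)) {
    stop("unknown residue code: ", if (!(a %in% known)) a else b,
         call. = FALSE)
  }
  if (a %in% gap || b %in% gap) return(0)
  if (a == b) return(1.0)
  ga <- vapply(scheme, function(g) a %in% g, logical(1))
  gb <- vapply(scheme, function(g) b %in% g, logical(1))
  if (any(ga & gb)) return(0.5)
  0
}

#' Definition of the H1 allosteric site
#'
#' The superficial allosteric site among helices C, E and H, defined by 18
#' residues in CYP2D6 numbering. Positions are 1-based residue numbers of
#' the ungapped reference sequence; each carries the expected one-letter
#' code so a mismatched reference is caught early.
#'
#' @param reference_id identifier of the reference sequence in the
#'   alignment, default `"CYP2D6"`.
#' @return A `site_definition` (see [site_definition()]).
#' @export
h1_site <- function(reference_id = "CYP2D6") {
  site_definition(
    reference_id = reference_id,
    positions = c(137, 138, 139, 140, 141, 142, 143, 144, 145, 146,
                  149, 189, 268, 269, 270, 271, 274, 277),
    codes = c("S", "T", "L", "R", "N", "L", "G", "L", "G", "K",
              "L", "L", "P", "R", "D", "L", "A", "A")
  )
}

#' Construct a site definition
#'
#' @param reference_id identifier of the reference sequence.
#' @param positions strictly increasing 1-based residue numbers on the
#'   ungapped reference.
#' @param codes expected one-letter codes at those positions.
#' @return A `site_definition` list.
#' @export
site_definition <- function(reference_id, positions, codes) {
  stopifnot(length(positions) == length(codes))
  if (any(diff(positions) <= 0)) {
    stop("site positions must be strictly increasing", call. = FALSE)
  }
  structure(list(reference_id = reference_id,
                 positions = as.integer(positions),
                 codes = toupper(codes)),
            class = "site_definition")
}

# Normalize an alignment argument: bio3d fasta object, path to an aligned
# FASTA, or a character matrix (rows = sequences) / named character vector
# of equal-length aligned strings.
.as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "fasta")) {
    m <- alignment$ali
  } else if (is.character(alignment) && length(alignment) == 1 &&
             file.exists(alignment)) {
    m <- bio3d::read.fasta(alignment)$ali
  } else if (is.matrix(alignment)) {
    m <- alignment
  } else if (is.character(alignment)) {
    if (length(unique(nchar(alignment))) != 1) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(alignment, ""))
    rownames(m) <- names(alignment)
  } else {
    stop("cannot interpret alignment input", call. = FALSE)
  }
  toupper(m)
}

#' Map a site definition onto every sequence of an alignment
#'
#' Locates, for each site position of the reference sequence, the alignment
#' column holding that (ungapped) reference position, verifies the reference
#' carries the expected residue there, and returns the residues found in the
#' same columns for every sequence. Gaps are returned as `"-"`.
#'
#' @param alignment aligned FASTA path, bio3d `fasta` object, character
#'   matrix, or named vector of aligned strings.
#' @param site a `site_definition`, default [h1_site()].
#' @return Character matrix: one row per sequence, one column per site
#'   position.
#' @export
map_site <- function(alignment, site = h1_site()) {
  m <- .as_alignment_matrix(alignment)
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  ref_row <- match(site$reference_id, rownames(m))
  if (is.na(ref_row)) {
    stop("reference sequence '", site$reference_id,
         "' not found in alignment", call. = FALSE)
  }
  ref <- m[ref_row, ]
  is_res <- !(ref %in% c("-", "."))
  ungapped_pos <- cumsum(is_res)
  cols <- vapply(site$positions, function(p) {
    w <- which(is_res & ungapped_pos == p)
    if (length(w) != 1) {
      stop("reference has no residue at position ", p, call. = FALSE)
    }
    w
  }, integer(1))
  found <- ref[cols]
  bad <- which(found != site$codes)
  if (length(bad) > 0) {
    stop("reference mismatch at site position ", site$positions[bad[1]],
         ": expected ", site$codes[bad[1]], ", found ", found[bad[1]],
         call. = FALSE)
  }
  out <- m[, cols, drop = FALSE]
  out[out == "."] <- "-"
  colnames(out) <- site$positions
  out
}

#' Pairwise site conservation and identity matrices
#'
#' For every pair of sequences, averages the residue pair score (1 / 0.5 /
#' 0) over the mapped site positions, and separately reports percent
#' identity over the site. The conservation value c is bounded by
#' identity/100 from below (each identical position contributes 1) and by
#' identity/100 + 0.5 (1 - identity/100) from above (every non-identical
#' position can contribute at most 0.5).
#'
#' @param alignment see [map_site()].
#' @param site a `site_definition`, default [h1_site()].
#' @param scheme group scheme, see [default_group_scheme()].
#' @return A `conservation_matrix`: list with `labels`, `c` (site-mean pair
#'   scores in \[0, 1\]) and `identity` (percent, \[0, 100\]), both symmetric
#'   with diagonal 1 and 100.
#' @export
site_conservation <- function(alignment, site = h1_site(),
                              scheme = default_group_scheme()) {
  .validate_scheme(scheme)
  mapped <- map_site(alignment, site)
  n <- nrow(mapped)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  labels <- rownames(mapped)
  cmat <- diag(1, n)
  imat <- diag(100, n)
  L <- ncol(mapped)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- vapply(seq_len(L), function(k) {
        pair_score(mapped[i, k], mapped[j, k], scheme)
      }, numeric(1))
      ident <- mapped[i, ] == mapped[j, ] & !(mapped[i, ] %in% "-")
      cmat[i, j] <- cmat[j, i] <- mean(sc)
      imat[i, j] <- imat[j, i] <- 100 * sum(ident) / L
    }
  }
  dimnames(cmat) <- dimnames(imat) <- list(labels, labels)
  structure(list(labels = labels, c = cmat, identity = imat),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("Site conservation over", length(x$labels), "sequences\n")
  print(round(x$c, 3))
  invisible(x)
}
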