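## Active-site signature classification for the AAAD family.
##
## Insect aromatic aldehyde synthases (DHPAAS) and aromatic amino acid
## decarboxylases (DDC) are distinguished by three active-site residues
## in reference numbering: Phe79-Tyr80-Asn192 marks aldehyde-synthase
## chemistry, while the reversed Tyr79-Phe80 motif together with His192
## marks a typical decarboxylase. Queries are mapped onto the reference
## numbering by global alignment.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

check_protein <- function(x, what) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop(sprintf("%s sequence is empty", what))
  bad <- setdiff(strsplit(x, "")[[1L]], .aa_alphabet)
  if (length(bad))
    stop(sprintf("%s sequence contains invalid letters: %s", what,
                 paste(unique(bad), collapse = ", ")))
  x
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + gap_extend * L`), scored with BLOSUM62 by
#' default. This is the position-mapping vehicle for
#' [residues_at_positions()]: the result carries, for every reference
#' position, the query position aligned to it (or `NA` at a gap).
#'
#' @param query,reference Protein sequences as uppercase one-letter
#'   strings (the 20 canonical residues plus `X`).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param substitution Substitution matrix name or matrix; default the
#'   BLOSUM62 table shipped with Biostrings.
#' @return An object of class `aa_alignment`: list with `query_aligned`
#'   and `ref_aligned` (equal-length gapped strings), `score`, and `map`
#'   (integer vector, reference position -> query position or `NA`).
#' @export
global_align <- function(query, reference, gap_open = 10, gap_extend = 1,
                         substitution = "BLOSUM62") {
  query <- check_protein(query, "query")
  reference <- check_protein(reference, "reference")
  submat <- if (is.matrix(substitution)) substitution
            else get_submatrix(substitution)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(reference),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  qa <- as.character(Biostrings::alignedPattern(pa))
  ra <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(qa, "")[[1L]]
  rc <- strsplit(ra, "")[[1L]]
  # reference position -> query position
  map <- rep(NA_integer_, nchar(reference))
  qpos <- cumsum(qc != "-")
  rpos <- cumsum(rc != "-")
  hit <- qc != "-" & rc != "-"
  map[rpos[hit]] <- qpos[hit]
  structure(list(query_aligned = qa, ref_aligned = ra,
                 score = Biostrings::score(pa), map = map,
                 query = query, reference = reference),
            class = "aa_alignment")
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Global alignment, score %.1f\n", x$score))
  cat("  query: ", x$query_aligned, "\n  ref:   ", x$ref_aligned, "\n",
      sep = "")
  invisible(x)
}

#' Query residues at reference-numbered positions
#'
#' @param aln An `aa_alignment` from [global_align()].
#' @param positions 1-based positions in reference coordinates; default
#'   the DHPAAS/DDC signature triad 79, 80, 192.
#' @return Named character vector of query residues; `"-"` where the
#'   query has a gap at that reference position.
#' @export
residues_at_positions <- function(aln, positions = c(79, 80, 192)) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (any(positions < 1L) || any(positions > length(aln$map)))
    stop("positions outside the reference sequence")
  qchars <- strsplit(aln$query, "")[[1L]]
  res <- ifelse(is.na(aln$map[positions]), "-", qchars[aln$map[positions]])
  names(res) <- paste0("pos", positions)
  res
}

#' Classify an active-site signature triad
#'
#' Applies the DHPAAS/DDC rule table to the residues found at reference
#' positions 79, 80 and 192:
#' \itemize{
#'   \item `(F, Y, N)` — DHPAAS-like (aldehyde synthase).
#'   \item `(Y, F, H)` — DDC-like (decarboxylase).
#'   \item any other combination of F/Y at 79-80 with N/H at 192 —
#'     intermediate; the note records which positions carry which
#'     archetype (e.g. the Tyr79-Tyr80 motif of some isoform-X2
#'     sequences).
#'   \item a gap, `X`, or any non-archetype residue at a triad position —
#'     undetermined.
#' }
#'
#' @param res79,res80,res192 Single residues (or `"-"` for a gap).
#' @return An object of class `signature_call`: list with `residues`,
#'   `label` (one of `"DHPAAS-like"`, `"DDC-like"`, `"intermediate"`,
#'   `"undetermined"`) and `note`.
#' @examples
#' classify_signature("F", "Y", "N")$label  # DHPAAS-like
#' classify_signature("Y", "Y", "N")$label  # intermediate
#' @export
classify_signature <- function(res79, res80, res192) {
  res <- c(res79 = res79, res80 = res80, res192 = res192)
  stopifnot(is.character(res), all(nchar(res) == 1L))
  valid <- list(res79 = c("F", "Y"), res80 = c("F", "Y"),
                res192 = c("N", "H"))
  bad <- !mapply(function(r, v) r %in% v, res, valid)
  if (any(bad)) {
    why <- ifelse(res[bad] %in% c("-", "X"), "undetermined", "non-archetype")
    note <- paste(sprintf("%s %s at position %s", why, res[bad],
                          sub("res", "", names(res)[bad])),
                  collapse = "; ")
    return(signature_call(res, "undetermined", note))
  }
  dhpaas <- c(res79 = "F", res80 = "Y", res192 = "N")
  ddc <- c(res79 = "Y", res80 = "F", res192 = "H")
  if (all(res == dhpaas))
    return(signature_call(res, "DHPAAS-like", "F79-Y80-N192 triad"))
  if (all(res == ddc))
    return(signature_call(res, "DDC-like", "Y79-F80-H192 triad"))
  arch <- ifelse(res == dhpaas, "DHPAAS", "DDC")
  note <- if (arch[["res79"]] == arch[["res80"]])
    sprintf("79/80 %s archetype with %s-type 192", arch[["res79"]],
            arch[["res192"]])
  else
    sprintf("79/80 mixed archetype (%s%s-%s%s); 192 %s-type",
            res[["res79"]], 79L, res[["res80"]], 80L, arch[["res192"]])
  signature_call(res, "intermediate", note)
}

signature_call <- function(res, label, note) {
  structure(list(residues = res, label = label, note = note),
            class = "signature_call")
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("%s (%s-%s-%s): %s\n", x$label, x$residues[1L],
              x$residues[2L], x$residues[3L], x$note))
  invisible(x)
}

#' Classify a set of sequences against a reference
#'
#' Aligns each query globally to the reference, extracts the residues at
#' the signature positions, and applies [classify_signature()].
#'
#' @param sequences Named character vector of protein sequences, or a
#'   path to a FASTA file (read with [Biostrings::readAAStringSet()]).
#' @param reference Reference protein sequence (uppercase string) whose
#'   numbering defines the signature positions.
#' @param positions Signature positions in reference numbering.
#' @param ... Passed to [global_align()].
#' @return A data frame with columns
#'   `id, res79, res80, res192, label, note`.
#' @export
classify_sequences <- function(sequences, reference,
                               positions = c(79, 80, 192), ...) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    aln <- global_align(sequences[[i]], reference, ...)
    res <- residues_at_positions(aln, positions)
    call <- classify_signature(res[[1L]], res[[2L]], res[[3L]])
    data.frame(id = ids[i], res79 = res[[1L]], res80 = res[[2L]],
               res192 = res[[3L]], label = call$label, note = call$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
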