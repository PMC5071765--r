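#' Homolog-selection criteria
#'
#' @param eMax e-value cutoff (strict `<`).
#' @param topK number of top-ranked hits considered per query.
#' @param rankBy how the "top k" hits are ordered when the hit table
#'   carries no rank column: `"evalue"` (default) or `"bitscore"`.
#' @return list of class `HomologyCriteria`.
#' @export
homologyCriteria <- function(eMax = 1e-10, topK = 10,
                             rankBy = c("evalue", "bitscore")) {
  if (eMax <= 0) stop("eMax must be > 0")
  if (topK < 1) stop("topK must be >= 1")
  structure(list(eMax = eMax, topK = topK, rankBy = match.arg(rankBy)),
            class = "HomologyCriteria")
}

#' Select the best homolog per query
#'
#' Restricts each query's hits to the `topK` best-ranked with e-value
#' strictly below `eMax`, then picks the hit with maximum percent
#' identity; ties are broken by smaller e-value, then lexicographic
#' subject id. Queries with no qualifying hit are unmapped (subject
#' NA), not an error. The result is invariant to input row order.
#'
#' @param hits data.frame with columns query, subject, pident, evalue
#'   and optionally rank (1..k per query; computed from `rankBy`
#'   otherwise).
#' @param criteria a [homologyCriteria()] object.
#' @return data.frame: query, subject (NA when unmapped), pident,
#'   evalue.
#' @examples
#' h <- data.frame(query = "q", subject = c("s1", "s2"),
#'                 pident = c(90, 95), evalue = c(1e-20, 1e-12),
#'                 rank = 1:2)
#' selectBestHomolog(h)$subject
#' @export
selectBestHomolog <- function(hits, criteria = homologyCriteria()) {
  stopifnot(all(c("query", "subject", "pident", "evalue") %in% names(hits)))
  if (!"rank" %in% names(hits)) {
    keyCol <- if (criteria$rankBy == "evalue") hits$evalue else -hits$bitscore
    hits$rank <- stats::ave(keyCol, hits$query,
                            FUN = function(v) rank(v, ties.method = "first"))
  }
  queries <- sort(unique(hits$query))
  pick <- lapply(queries, function(q) {
    h <- hits[hits$query == q & hits$rank <= criteria$topK &
                hits$evalue < criteria$eMax, , drop = FALSE]
    if (!nrow(h))
      return(data.frame(query = q, subject = NA_character_,
                        pident = NA_real_, evalue = NA_real_))
    h <- h[order(-h$pident, h$evalue, h$subject), , drop = FALSE]
    data.frame(query = q, subject = h$subject[1], pident = h$pident[1],
               evalue = h$evalue[1])
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}

#' Hypergeometric term over-representation
#'
#' One-sided enrichment test per term: with a background universe of
#' size N, a term of size K (members intersected with the background),
#' and a query of size n, the p-value is `P[X >= overlap]` for
#' `X ~ Hypergeometric(N, K, n)` — Fisher's exact test, greater.
#' P-values are Benjamini-Hochberg adjusted across terms and the
#' result is sorted by p.
#'
#' @param query character vector of ids (must be a subset of
#'   `background`).
#' @param annotations named list of term member-id vectors (see
#'   [readGmt()]).
#' @param background character vector: the id universe.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"` (doubled one-sided tail, capped at 1).
#' @return data.frame: term, termSize, overlap, p, padj.
#' @examples
#' enrichTerms(c("a", "b"), list(T1 = c("a", "b", "c")),
#'             background = letters[1:10])
#' @export
enrichTerms <- function(query, annotations, background,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background))
    stop("query must be a subset of the background universe")
  N <- length(background); n <- length(query)
  rows <- lapply(names(annotations), function(tm) {
    members <- intersect(unique(annotations[[tm]]), background)
    if (!length(members)) {
      warning("term ", tm, " has no background members; skipped")
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    if (alternative == "two.sided")
      p <- min(1, 2 * min(p, phyper(k, K, N - K, n)))
    data.frame(term = tm, termSize = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), termSize = integer(),
                      overlap = integer(), p = numeric(), padj = numeric()))
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write GMT annotation files
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `name`, `description`, then member ids.
#'
#' @param path file path.
#' @return `readGmt()`: named list of member-id vectors with a
#'   `descriptions` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' @rdname readGmt
#' @param sets named list of member-id vectors; an optional
#'   `descriptions` attribute (named character) fills field two.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular alignment output (12-column BLAST dialect)
#'
#' Reads the standard 12-column tabular hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score) and adds a
#' per-query rank by e-value.
#'
#' @param path file path.
#' @return data.frame with the 12 named columns plus `rank`.
#' @export
readBlastTab <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, sep = "\t", quote = "", col.names = cols,
                    stringsAsFactors = FALSE)
  tab$rank <- stats::ave(tab$evalue, tab$query,
                         FUN = function(v) rank(v, ties.method = "first"))
  tab
}
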