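# Metabolite-set over-representation analysis (hypergeometric ORA) over
# GMT pathway files. The packaged demo pathway file is a curated resource
# built from this package's own metabolite vocabulary, not a KEGG export.

#' Read pathway sets from a GMT file
#'
#' One pathway per line: id, name, then member metabolite ids, tab
#' separated. Empty pathway lines are skipped with a warning; duplicate
#' members within a pathway are collapsed.
#'
#' @param path GMT file path.
#' @return named list of list(id, name, members) with class
#'   \code{pathway_set}.
#' @export
readPathways <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      warning("skipping GMT line ", i, ": pathway with no members")
      next
    }
    id <- parts[1]
    if (id %in% names(out)) stop("duplicate pathway id: ", id)
    out[[id]] <- list(id = id, name = parts[2],
                      members = unique(parts[-(1:2)]))
  }
  structure(out, class = "pathway_set")
}

#' Write pathway sets to a GMT file
#' @param pathways a \code{pathway_set}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePathways <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$id, p$name, p$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and
#' each pathway, restricted to the supplied background (all quantified
#' metabolites); Benjamini-Hochberg adjustment across tested pathways.
#' Pathways with no background overlap are skipped.
#'
#' @param hits metabolite ids selected by the screen (subset of
#'   \code{background}).
#' @param background metabolite ids of the quantified universe.
#' @param pathways a \code{pathway_set} from \code{\link{readPathways}}.
#' @return data.frame(pathway, name, overlap, pathway_size,
#'   background_size, n_hits, p, p_adj) sorted by p; empty for empty
#'   \code{hits}.
#' @export
ora <- function(hits, background, pathways) {
  hits <- unique(hits)
  background <- unique(background)
  bad <- setdiff(hits, background)
  if (length(bad))
    stop("hits not contained in background: ", paste(bad, collapse = ", "))
  empty <- data.frame(pathway = character(), name = character(),
                      overlap = integer(), pathway_size = integer(),
                      background_size = integer(), n_hits = integer(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$members, background)
    m <- length(members)
    if (m == 0) return(NULL)
    k <- length(intersect(members, hits))
    p <- phyper(k - 1, m, length(background) - m, length(hits),
                lower.tail = FALSE)
    data.frame(pathway = pw$id, name = pw$name, overlap = k,
               pathway_size = m, background_size = length(background),
               n_hits = length(hits), p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}
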