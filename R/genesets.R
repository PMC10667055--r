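# Gene-set collections (GMT format) and the packaged m6A regulator list.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes. Duplicate genes within a set are removed; empty sets raise
#' an error.
#'
#' @param path File path.
#' @return Named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("GMT line with no genes: '%s'",
                   substr(l, 1L, 40L)), call. = FALSE)
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in GMT", call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The 23 m6A regulator genes
#'
#' The regulator list as assembled from the literature, spanning the
#' methyltransferase "writers", demethylase "erasers" and m6A-binding
#' "readers". Two entries circulate under variant spellings; see
#' [m6a_regulator_aliases()]. Set `resolve_aliases = TRUE` to map them to
#' their canonical HGNC symbols.
#'
#' @param resolve_aliases Replace variant spellings by canonical symbols.
#' @return Character vector of 23 gene symbols.
#' @export
m6a_regulators <- function(resolve_aliases = FALSE) {
  g <- read_gmt(system.file("extdata", "m6a_regulators.gmt",
                            package = "m6aTME"))[["M6A_REGULATORS"]]
  if (resolve_aliases) {
    al <- m6a_regulator_aliases()
    hit <- match(g, al$listed)
    g[!is.na(hit)] <- al$canonical[hit[!is.na(hit)]]
  }
  g
}

#' Alias table for variant regulator spellings
#'
#' The shipped regulator list preserves the spellings as originally
#' printed; this table records the canonical HGNC symbol each variant is
#' understood to denote. Gene-id matching elsewhere in the package is
#' exact-string, so callers working with canonical symbols should resolve
#' aliases explicitly.
#'
#' @return Data frame with columns `listed`, `canonical`.
#' @export
m6a_regulator_aliases <- function() {
  data.frame(listed = c("L RPPRC", "ALKBH"),
             canonical = c("LRPPRC", "ALKBH5"),
             stringsAsFactors = FALSE)
}

#' Functional roles of the m6A regulators
#'
#' @return Data frame with columns `gene` (canonical symbol) and `role`
#'   (`writer`, `eraser` or `reader`).
#' @export
m6a_regulator_roles <- function() {
  writers <- c("METTL3", "METTL14", "METTL16", "WTAP", "VIRMA", "ZC3H13",
               "RBM15", "RBM15B")
  erasers <- c("FTO", "ALKBH5")
  readers <- c("YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2", "YTHDF3", "HNRNPC",
               "FMR1", "LRPPRC", "HNRNPA2B1", "IGFBP1", "IGFBP2", "IGFBP3",
               "RBMX")
  data.frame(gene = c(writers, erasers, readers),
             role = rep(c("writer", "eraser", "reader"),
                        c(length(writers), length(erasers), length(readers))),
             stringsAsFactors = FALSE)
}

#' Names of the 28 immune cell types scored by ssGSEA
#'
#' The conventional pan-cancer immunome panel of 28 tumor-infiltrating
#' lymphocyte populations. The package ships only the cell-type names; the
#' packaged GMT under `extdata/immune28_synthetic.gmt` carries synthetic
#' placeholder gene memberships for testing and must be replaced by a real
#' signature collection for biological use.
#'
#' @return Character vector of 28 cell-type names.
#' @export
immune_cell_types <- function() {
  c("Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
    "Activated dendritic cell", "CD56bright natural killer cell",
    "CD56dim natural killer cell", "Central memory CD4 T cell",
    "Central memory CD8 T cell", "Effector memory CD4 T cell",
    "Effector memory CD8 T cell", "Eosinophil", "Gamma delta T cell",
    "Immature B cell", "Immature dendritic cell", "MDSC", "Macrophage",
    "Mast cell", "Memory B cell", "Monocyte", "Natural killer T cell",
    "Natural killer cell", "Neutrophil", "Plasmacytoid dendritic cell",
    "Regulatory T cell", "T follicular helper cell", "Type 1 T helper cell",
    "Type 17 T helper cell", "Type 2 T helper cell")
}

#' Packaged synthetic immune signature collection
#'
#' Loads the shipped 28-set GMT whose gene memberships are synthetic
#' placeholders (useful for exercising the enrichment machinery); supply a
#' real signature GMT via [read_gmt()] for biological analyses.
#'
#' @return Named list of 28 character vectors.
#' @export
immune_signatures_synthetic <- function() {
  read_gmt(system.file("extdata", "immune28_synthetic.gmt",
                       package = "m6aTME"))
}
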