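# Controlled gene vocabulary for bivalve mitochondrial genomes.

.PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
.RRNA_NAMES <- c("rrnS", "rrnL")
.TRNA_NAMES <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                 "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                 "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                 "trnY")
.ORFAN_NAMES <- c("F-orf", "M-orf", "M-orf2", "H-orf")

#' Controlled vocabulary of mitochondrial gene names
#'
#' The standard metazoan mitochondrial gene set (13 protein-coding genes,
#' 2 rRNAs, 22 tRNAs with Leu/Ser paralogue disambiguation) plus the
#' lineage-specific ORFan genes of DUI freshwater mussels (F-orf, M-orf,
#' M-orf2, H-orf).
#'
#' @return A data frame with columns `name` and `kind`
#'   (`"PCG"`, `"rRNA"`, `"tRNA"` or `"ORFan"`).
#' @export
#' @examples
#' nrow(mt_gene_vocabulary())  # 37 standard genes + 4 ORFans
mt_gene_vocabulary <- function() {
  data.frame(
    name = c(.PCG_NAMES, .RRNA_NAMES, .TRNA_NAMES, .ORFAN_NAMES),
    kind = c(rep("PCG", length(.PCG_NAMES)),
             rep("rRNA", length(.RRNA_NAMES)),
             rep("tRNA", length(.TRNA_NAMES)),
             rep("ORFan", length(.ORFAN_NAMES))),
    stringsAsFactors = FALSE
  )
}

#' Gene-name synonym table
#'
#' Maps the common annotation synonyms found in GenBank records (COI, ND2,
#' 16S, ATPase6, tRNA-Asp, ...) onto the controlled vocabulary of
#' [mt_gene_vocabulary()]. Shipped as a plain-text table in
#' `extdata/gene_synonyms.tsv`; matching is case-insensitive.
#'
#' @return A data frame with columns `synonym` and `name`.
#' @export
gene_synonyms <- function() {
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitorfan")
  if (!nzchar(path)) stop("synonym table not found")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Normalize a gene label to the controlled vocabulary
#'
#' @param x Character vector of raw gene labels.
#' @return Character vector of vocabulary names; labels with no match are
#'   returned unchanged with a warning (callers typically record such
#'   features as kind `"other"`).
#' @export
normalize_gene_name <- function(x) {
  voc <- mt_gene_vocabulary()$name
  syn <- gene_synonyms()
  out <- character(length(x))
  for (i in seq_along(x)) {
    raw <- trimws(x[i])
    hit <- voc[match(tolower(raw), tolower(voc))]
    if (is.na(hit)) {
      j <- match(tolower(raw), tolower(syn$synonym))
      hit <- if (is.na(j)) NA_character_ else syn$name[j]
    }
    if (is.na(hit)) {
      if (!grepl("^(pseudo:|other)", raw))
        warning("unknown gene label '", raw, "' kept as-is", call. = FALSE)
      hit <- raw
    }
    out[i] <- hit
  }
  out
}

# Infer the feature kind from a vocabulary name.
infer_kind <- function(name) {
  kind <- character(length(name))
  kind[name %in% .PCG_NAMES] <- "PCG"
  kind[name %in% .RRNA_NAMES] <- "rRNA"
  kind[name %in% .TRNA_NAMES] <- "tRNA"
  kind[name %in% .ORFAN_NAMES] <- "ORFan"
  kind[startsWith(name, "pseudo:")] <- "pseudogene_fragment"
  kind[kind == ""] <- "other"
  kind
}
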