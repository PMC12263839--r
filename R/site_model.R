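BASES <- c("A", "C", "G", "T")

# Per-codon (nN, nS) lookup for the 61 sense codons of the standard genetic
# code, computed once per session. Equal substitution weighting: each of the
# nine single-nucleotide neighbors contributes 1/3 of a site at its position.
codon_table_env <- new.env(parent = emptyenv())

codon_site_lookup <- function() {
  if (!is.null(codon_table_env$tab)) return(codon_table_env$tab)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  nS <- vapply(sense, function(cod) {
    aa <- gc[[cod]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        # substitutions creating a stop are protein-changing, hence nonsyn
        if (gc[[alt]] == aa) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  codon_table_env$tab <- data.frame(codon = sense, nN = 3 - nS, nS = nS,
                                    stringsAsFactors = FALSE,
                                    row.names = sense)
  codon_table_env$tab
}

#' Nonsynonymous and synonymous site counts of one codon
#'
#' For each codon position, the synonymous site fraction is the number of the
#' three possible single-nucleotide substitutions that preserve the amino
#' acid, divided by three; substitutions that create a stop codon count as
#' nonsynonymous. By construction `nN + nS = 3` for every sense codon.
#'
#' @param codon 3-letter string over A/C/G/T; stop codons are rejected.
#' @return named numeric vector `c(nN = , nS = )`.
#' @examples
#' codon_site_counts("TTT")  # nN = 8/3, nS = 1/3
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon))
    stop("codon must be 3 letters over {A,C,G,T}: ", codon)
  if (Biostrings::GENETIC_CODE[[codon]] == "*")
    stop("stop codons are excluded from site counting: ", codon)
  tab <- codon_site_lookup()
  c(nN = tab[codon, "nN"], nS = tab[codon, "nS"])
}

#' Build a site table from coding sequences
#'
#' Computes per-gene and genome-total counts of nonsynonymous (nN) and
#' synonymous (nS) sites by summing [codon_site_counts()] over every codon,
#' treating the exome as one concatenated sequence for the totals. A
#' terminal stop codon is trimmed; genes whose length is not a multiple of
#' three, or that contain internal stops or ambiguous bases, are skipped
#' with a warning rather than repaired.
#'
#' @param cds either a path to a FASTA file (one record per gene, identifier
#'   taken as the gene symbol), a [Biostrings::DNAStringSet], or a named
#'   character vector of sequences.
#' @return object of class `site_table`: list with `per_gene` (data.frame
#'   `gene`, `nN`, `nS`, `length_nt`), `totals` (list `nN_total`, `nS_total`,
#'   `length_total`) and `skipped` (character vector of skipped genes).
#' @export
build_site_table <- function(cds) {
  if (is.character(cds) && length(cds) == 1 && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  seqs <- stats::setNames(toupper(as.character(cds)), names(cds))
  if (length(seqs) == 0) stop("no sequences provided")
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  tab <- codon_site_lookup()
  skipped <- character(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    gene <- names(seqs)[i]
    s <- seqs[[i]]
    len <- nchar(s)
    if (len >= 3 && substr(s, len - 2, len) %in% stops) {
      s <- substr(s, 1, len - 3)
      len <- len - 3
    }
    if (len == 0 || len %% 3 != 0 || grepl("[^ACGT]", s)) {
      skipped <- c(skipped, gene)
      next
    }
    codons <- substring(s, seq(1, len, 3), seq(3, len, 3))
    if (any(codons %in% stops)) {
      skipped <- c(skipped, gene)
      next
    }
    rows[[i]] <- data.frame(gene = gene,
                            nN = sum(tab[codons, "nN"]),
                            nS = sum(tab[codons, "nS"]),
                            length_nt = len, stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_gene) || nrow(per_gene) == 0)
    stop("no valid coding sequences after validation")
  if (length(skipped))
    warning("skipped ", length(skipped), " gene(s) failing validation: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  rownames(per_gene) <- per_gene$gene
  st <- list(per_gene = per_gene,
             totals = list(nN_total = sum(per_gene$nN),
                           nS_total = sum(per_gene$nS),
                           length_total = sum(per_gene$length_nt)),
             skipped = skipped)
  class(st) <- "site_table"
  st
}

#' @export
print.site_table <- function(x, ...) {
  cat("Site table:", nrow(x$per_gene), "genes,",
      x$totals$length_total, "coding nt\n")
  cat(sprintf("  nN = %.2f, nS = %.2f (nN/nS = %.3f)\n",
              x$totals$nN_total, x$totals$nS_total,
              x$totals$nN_total / x$totals$nS_total))
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "genes\n")
  invisible(x)
}

#' Serialize a site table to TSV
#'
#' Writes per-gene rows plus a trailing `.TOTAL` row.
#'
#' @param site_table a `site_table`.
#' @param path output path.
#' @export
write_site_table <- function(site_table, path) {
  out <- rbind(site_table$per_gene,
               data.frame(gene = ".TOTAL",
                          nN = site_table$totals$nN_total,
                          nS = site_table$totals$nS_total,
                          length_nt = site_table$totals$length_total))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return a `site_table`.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tot <- df[df$gene == ".TOTAL", ]
  per_gene <- df[df$gene != ".TOTAL", ]
  rownames(per_gene) <- per_gene$gene
  st <- list(per_gene = per_gene,
             totals = list(nN_total = tot$nN, nS_total = tot$nS,
                           length_total = tot$length_nt),
             skipped = character(0))
  class(st) <- "site_table"
  st
}
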