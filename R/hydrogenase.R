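#' Load hydrogenase motif rules
#'
#' Reads a TSV of regular-expression rules over amino-acid sequence, one row
#' per motif, with a metal class (FeFe or NiFe), an optional group hint and a
#' `probe` exemplar used by the proteome simulator. The bundled default
#' carries the canonical FeFe H-cluster (L1/L2/L3) and NiFe CxxC
#' nickel-binding motifs from the standard hydrogenase literature; replace
#' the file to use project-specific patterns.
#'
#' @param path TSV with columns `name, metal_class, pattern, group_hint,
#'   probe, source`; `NULL` for the bundled defaults.
#' @return data.frame of class `motif_rules`.
#' @export
load_motif_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hydrogenase_motifs.tsv", package = "syntherm")
  }
  rules <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("name", "metal_class", "pattern")
  if (!all(need %in% names(rules))) {
    stop("rule file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!rules$metal_class %in% c("FeFe", "NiFe"))) {
    stop("metal_class must be FeFe or NiFe")
  }
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({ grepl(rules$pattern[i], "A", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("rule does not compile: ", rules$name[i])
    if ("probe" %in% names(rules) && !is.na(rules$probe[i]) &&
        !grepl(rules$pattern[i], rules$probe[i], perl = TRUE)) {
      stop("probe does not match its own pattern for rule ", rules$name[i])
    }
  }
  class(rules) <- c("motif_rules", "data.frame")
  rules
}

#' Read a proteome with gene order
#'
#' Combines a protein FASTA (headers are gene ids) with a gene-order table
#' giving each coding sequence's contig and 0-based ordinal position.
#'
#' @param fasta_path protein FASTA.
#' @param gene_order_path TSV `gene_id, contig, ordinal, product`.
#' @return data.frame `gene_id, contig, ordinal, product, sequence`.
#' @export
read_proteome <- function(fasta_path, gene_order_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  order_tab <- read.delim(gene_order_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "ordinal", "product")
  if (!all(need %in% names(order_tab))) {
    stop("gene-order table must have columns: ", paste(need, collapse = ", "))
  }
  idx <- match(order_tab$gene_id, ids)
  if (anyNA(idx)) {
    stop("gene ids missing from FASTA: ",
         paste(utils::head(order_tab$gene_id[is.na(idx)], 3), collapse = ", "))
  }
  records <- order_tab
  records$sequence <- as.character(aa)[idx]
  validate_gene_records(records)
  records
}

validate_gene_records <- function(records) {
  need <- c("gene_id", "contig", "ordinal", "product", "sequence")
  if (!all(need %in% names(records))) {
    stop("gene records must have columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(records[, c("contig", "ordinal")])
  if (any(dup)) stop("duplicated ordinal within contig")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", records$sequence)
  if (any(bad)) {
    stop("sequence with letters outside the amino-acid alphabet: ",
         records$gene_id[bad][1])
  }
  invisible(records)
}

#' Scan a proteome for hydrogenase binding motifs
#'
#' Matches every rule against every protein and emits one call per gene with
#' at least one hit. Genes matching rules of both metal classes are flagged
#' `ambiguous` with both hit sets retained rather than resolved by
#' precedence. The group is the metal class plus the rules' group hint when
#' all matched rules of the class agree (e.g. `"FeFe A"`); sub-class labels
#' such as `NiFe 1a` require [refine_groups()].
#'
#' @param records gene records as from [read_proteome()].
#' @param rules a [load_motif_rules()] table.
#' @return data.frame of class `hydrogenase_calls`: `gene_id, contig,
#'   ordinal, metal_class, group, ambiguous, nuof_gene, nuof_distance` plus a
#'   `motif_hits` list-column of per-call data.frames `rule, start, end`.
#' @export
scan_motifs <- function(records, rules) {
  validate_gene_records(records)
  empty <- data.frame(gene_id = character(), contig = character(),
                      ordinal = integer(), metal_class = character(),
                      group = character(), ambiguous = logical(),
                      nuof_gene = character(), nuof_distance = integer(),
                      stringsAsFactors = FALSE)
  empty$motif_hits <- list()
  if (nrow(records) == 0) return(structure(empty, class = c("hydrogenase_calls", "data.frame")))
  calls <- lapply(seq_len(nrow(records)), function(i) {
    seq_i <- records$sequence[i]
    hits <- lapply(seq_len(nrow(rules)), function(j) {
      m <- gregexpr(rules$pattern[j], seq_i, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      data.frame(rule = rules$name[j], start = as.integer(m),
                 end = as.integer(m) + attr(m, "match.length") - 1L,
                 metal_class = rules$metal_class[j],
                 group_hint = if ("group_hint" %in% names(rules))
                   rules$group_hint[j] else NA_character_,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) return(NULL)
    classes <- unique(hits$metal_class)
    ambiguous <- length(classes) > 1
    metal <- if (ambiguous) "ambiguous" else classes
    hint <- unique(hits$group_hint[!is.na(hits$group_hint)])
    group <- if (ambiguous) "ambiguous"
             else if (length(hint) == 1) paste(metal, hint) else metal
    row <- data.frame(gene_id = records$gene_id[i], contig = records$contig[i],
                      ordinal = records$ordinal[i], metal_class = metal,
                      group = group, ambiguous = ambiguous,
                      nuof_gene = NA_character_, nuof_distance = NA_integer_,
                      stringsAsFactors = FALSE)
    row$motif_hits <- list(hits[, c("rule", "start", "end")])
    row
  })
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) calls <- empty
  calls <- calls[order(calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("hydrogenase_calls", "data.frame"))
}

#' Upgrade FeFe type-A calls near NuoF to bifurcating A3
#'
#' FeFe type-A hydrogenases residing within 5 coding sequences (inclusive
#' ordinal distance, same contig, strand-agnostic) of a gene whose product
#' annotation matches the NuoF pattern are reclassified `"FeFe A3"`, with
#' the nearest NuoF gene and its CDS distance recorded as proximity
#' evidence. Idempotent; without any NuoF gene the calls pass through
#' unchanged with a message.
#'
#' @param calls a [scan_motifs()] result.
#' @param records the gene records the calls came from.
#' @param nuof_pattern regular expression on the product label (default
#'   matches "NuoF"/"nuoF").
#' @param max_distance inclusive CDS distance (default 5).
#' @return the calls with A3 upgrades applied.
#' @export
assign_a3_by_proximity <- function(calls, records,
                                   nuof_pattern = "\\bnuoF\\b",
                                   max_distance = 5) {
  nuof <- records[grepl(nuof_pattern, records$product, ignore.case = TRUE), ,
                  drop = FALSE]
  if (nrow(nuof) == 0) {
    message("no NuoF gene in annotation; calls unchanged")
    return(calls)
  }
  is_fefe_a <- calls$metal_class == "FeFe" &
    calls$group %in% c("FeFe A", "FeFe A3")
  for (i in which(is_fefe_a)) {
    same <- nuof[nuof$contig == calls$contig[i], , drop = FALSE]
    if (nrow(same) == 0) next
    d <- abs(same$ordinal - calls$ordinal[i])
    j <- which.min(d)
    if (d[j] <= max_distance) {
      calls$group[i] <- "FeFe A3"
      calls$nuof_gene[i] <- same$gene_id[j]
      calls$nuof_distance[i] <- as.integer(d[j])
    }
  }
  calls
}

#' Refine call groups from an external annotation
#'
#' Binding motifs alone cannot resolve groups below the metal class
#' (e.g. NiFe 1a vs 3b vs 4e); this merges an external group column, such as
#' an HydDB export, into the calls. Proximity-derived `FeFe A3` labels are
#' kept unless the external table disagrees explicitly.
#'
#' @param calls a [scan_motifs()] result.
#' @param groups data.frame `gene_id, group`.
#' @return calls with refined `group`.
#' @export
refine_groups <- function(calls, groups) {
  idx <- match(calls$gene_id, groups$gene_id)
  hit <- !is.na(idx)
  calls$group[hit] <- groups$group[idx[hit]]
  calls
}

#' Per-genome hydrogenase repertoire counts
#'
#' @param calls a [scan_motifs()] result (typically after
#'   [assign_a3_by_proximity()] and [refine_groups()]).
#' @param genome_map data.frame `gene_id, genome` mapping every called gene
#'   to exactly one genome.
#' @return dense zero-filled count matrix, genomes as rows and groups as
#'   columns, both in lexicographic order.
#' @export
summarize_repertoire <- function(calls, genome_map) {
  if (nrow(calls) == 0) return(matrix(0L, 0, 0))
  idx <- match(calls$gene_id, genome_map$gene_id)
  if (anyNA(idx)) {
    stop("gene mapped to no genome: ", calls$gene_id[is.na(idx)][1])
  }
  genome <- genome_map$genome[idx]
  tab <- table(genome = genome, group = calls$group)
  tab <- tab[order(rownames(tab)), order(colnames(tab)), drop = FALSE]
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Write hydrogenase calls as a tidy TSV
#'
#' @param calls a [scan_motifs()] result.
#' @param path output path.
#' @export
write_hydrogenase_calls <- function(calls, path) {
  flat <- calls
  flat$motif_hits <- vapply(calls$motif_hits, function(h) {
    paste(sprintf("%s:%d-%d", h$rule, h$start, h$end), collapse = ";")
  }, character(1))
  write.table(as.data.frame(flat), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
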