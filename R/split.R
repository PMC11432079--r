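#' Split a gene's proxy regions into standalone pseudo-genes
#'
#' Rewrites the annotation so that each proxy region becomes a separately
#' countable pseudo-gene (fresh `gene_id`, `transcript_id` and `gene_name`)
#' while all exonic bases outside the proxies remain under the original gene
#' — the annotation edit that makes a gene-level 10X quantifier report
#' 3'-distinguishable isoforms as if they were separate genes. Records of all
#' other genes are preserved verbatim.
#'
#' Exon-level records of the source gene overlapping a proxy are trimmed to
#' their non-proxy bases (an exon fully inside a proxy is removed, a
#' read-through exon has its boundary edited); transcript and gene spans are
#' recomputed from the retained exons, and transcripts left without exons are
#' dropped. Exonic bases are conserved: retained + pseudo-gene exon bases
#' equal the original gene's exon bases, disjointly.
#'
#' @param annotation A `gtf_annotation` from [read_gtf()].
#' @param gene_id Source gene to split.
#' @param proxies Named list of `proxy_region` objects ([proxy_regions()]).
#' @param gene_name_map Optional named character vector mapping group names to
#'   output `gene_name`s (default: the group name itself, as in naming the
#'   pseudo-genes bare "THRA1"/"THRA2").
#' @param id_scheme Function `(source_gene_id, group_name) -> new gene_id`;
#'   default `"<gene_id>-<GROUP>"`.
#' @param transcript_scheme Function giving the pseudo-transcript id; default
#'   `"<new gene_id>-T1"`.
#' @param include_auxiliary Also emit CDS/UTR/stop-codon records of the source
#'   gene that fall inside a proxy, re-attributed to the pseudo-gene. Default
#'   `FALSE`: gene/transcript/exon records are what 10X-style reference
#'   builders count.
#' @param on_existing `"error"` (default) aborts if the pseudo-gene ids are
#'   already present (e.g. the annotation was already split); `"skip"` returns
#'   the annotation unchanged. Never a double split.
#' @param source_label GTF `source` column for new records.
#' @return A list with `annotation` (the edited `gtf_annotation`) and `plan`
#'   (a `split_plan`: ids, per-group intervals and retained intervals,
#'   serializable with [write_split_plan()]).
#' @export
split_gene <- function(annotation, gene_id, proxies,
                       gene_name_map = NULL,
                       id_scheme = function(gid, grp) paste0(gid, "-", grp),
                       transcript_scheme = function(new_gid, grp) paste0(new_gid, "-T1"),
                       include_auxiliary = FALSE,
                       on_existing = c("error", "skip"),
                       source_label = "exonproxy") {
  on_existing <- match.arg(on_existing)
  if (!inherits(annotation, "gtf_annotation"))
    stop("'annotation' must come from read_gtf()")
  gene <- annotation$genes[[gene_id]]
  if (is.null(gene)) stop("gene ", gene_id, " not found in annotation")

  group_names <- vapply(proxies, `[[`, character(1), "group_name")
  new_gids <- vapply(group_names, function(g) id_scheme(gene_id, g), character(1))
  new_tids <- vapply(seq_along(group_names),
                     function(i) transcript_scheme(new_gids[i], group_names[i]),
                     character(1))
  if (anyDuplicated(new_gids) || anyDuplicated(new_tids))
    stop("id scheme generated duplicate pseudo-gene ids")
  rec <- annotation$records
  existing <- intersect(new_gids, unique(rec$gene_id))
  if (length(existing) > 0L) {
    if (on_existing == "skip") {
      message("pseudo-gene id(s) already present (", paste(existing, collapse = ", "),
              "); annotation returned unchanged")
      return(list(annotation = annotation, plan = NULL))
    }
    stop("pseudo-gene id(s) already present in annotation: ",
         paste(existing, collapse = ", "),
         " (already split? use on_existing = \"skip\" for a no-op)")
  }

  ivs <- lapply(proxies, function(p) strip_seqinfo(p$intervals))
  all_proxy <- do.call(c, unname(ivs))
  if (!IRanges::isDisjoint(IRanges::ranges(all_proxy)))
    stop("proxy regions must be pairwise disjoint")
  all_proxy <- merge_intervals(all_proxy)

  src <- rec$gene_id == gene_id
  src_rows <- rec[src, , drop = FALSE]
  other_rows <- rec[!src, , drop = FALSE]

  exonic_feats <- c("exon", "CDS", "five_prime_utr", "three_prime_utr",
                    "stop_codon", "start_codon")
  retained <- trim_source_rows(src_rows, all_proxy, exonic_feats, gene$strand)

  # pseudo-gene records
  biotype <- gene$biotype
  pseudo <- list()
  for (i in seq_along(proxies)) {
    grp <- group_names[i]
    gname <- if (!is.null(gene_name_map) && grp %in% names(gene_name_map))
      unname(gene_name_map[[grp]]) else grp
    iv <- BiocGenerics::sort(ivs[[i]])
    gattrs <- list(gene_id = new_gids[i], gene_name = gname)
    if (!is.na(biotype)) gattrs$gene_biotype <- biotype
    tattrs <- c(gattrs[1], list(transcript_id = new_tids[i]), gattrs[-1])
    span_s <- min(BiocGenerics::start(iv)); span_e <- max(BiocGenerics::end(iv))
    pseudo[[length(pseudo) + 1L]] <- make_gtf_record(
      gene$seqname, source_label, "gene", span_s, span_e, gene$strand, gattrs)
    pseudo[[length(pseudo) + 1L]] <- make_gtf_record(
      gene$seqname, source_label, "transcript", span_s, span_e, gene$strand, tattrs)
    ranks <- exon_rank(iv, gene$strand)
    for (j in seq_along(iv)) {
      eattrs <- tattrs
      eattrs$exon_number <- ranks[j]
      pseudo[[length(pseudo) + 1L]] <- make_gtf_record(
        gene$seqname, source_label, "exon",
        BiocGenerics::start(iv)[j], BiocGenerics::end(iv)[j],
        gene$strand, eattrs)
    }
    if (include_auxiliary) {
      aux <- src_rows[src_rows$feature %in%
                        c("CDS", "five_prime_utr", "three_prime_utr", "stop_codon"), ,
                      drop = FALSE]
      for (j in seq_len(nrow(aux))) {
        arow <- genomic_intervals(gene$seqname, aux$start[j], aux$end[j], gene$strand)
        inside <- GenomicRanges::intersect(arow, iv)
        for (k in seq_along(inside)) {
          pseudo[[length(pseudo) + 1L]] <- make_gtf_record(
            gene$seqname, source_label, aux$feature[j],
            BiocGenerics::start(inside)[k], BiocGenerics::end(inside)[k],
            gene$strand, tattrs, frame = aux$frame[j])
        }
      }
    }
  }
  pseudo <- do.call(rbind, pseudo)

  # invariant: pseudo exon bases never overlap retained exon bases
  ret_ex <- retained[retained$feature == "exon", , drop = FALSE]
  if (nrow(ret_ex) > 0L) {
    ret_gr <- genomic_intervals(gene$seqname, ret_ex$start, ret_ex$end, gene$strand)
    if (length(GenomicRanges::intersect(merge_intervals(ret_gr), all_proxy)) > 0L)
      stop("internal error: proxy region overlaps a retained exon of ", gene_id)
  }

  out_rec <- rbind(other_rows, retained, pseudo)
  out_rec$line <- NULL
  out_rec$line <- NA_integer_
  out <- new_gtf_annotation(out_rec)

  plan <- structure(list(
    source_gene_id = gene_id,
    source_gene_name = gene$gene_name,
    groups = lapply(seq_along(proxies), function(i) {
      iv <- ivs[[i]]
      list(group = group_names[i], gene_id = unname(new_gids[i]),
           transcript_id = unname(new_tids[i]),
           gene_name = if (!is.null(gene_name_map) && group_names[i] %in% names(gene_name_map))
             unname(gene_name_map[[group_names[i]]]) else group_names[i],
           intervals = granges_to_df(iv))
    }),
    retained = granges_to_df(retained_exon_bases(retained, gene)),
    options = list(include_auxiliary = include_auxiliary,
                   source_label = source_label)
  ), class = "split_plan")
  list(annotation = out, plan = plan)
}

retained_exon_bases <- function(retained, gene) {
  ex <- retained[retained$feature == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(GenomicRanges::GRanges())
  merge_intervals(genomic_intervals(gene$seqname, ex$start, ex$end, gene$strand))
}

granges_to_df <- function(gr) {
  data.frame(seqname = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

# Trim the source gene's rows against the proxy bases: exon-level rows keep
# their non-proxy pieces (attributes preserved verbatim), transcript and gene
# rows are re-spanned over the retained exons, empty transcripts are dropped.
trim_source_rows <- function(src_rows, all_proxy, exonic_feats, strand) {
  keep <- list()
  exon_by_tx <- list()
  for (j in seq_len(nrow(src_rows))) {
    row <- src_rows[j, , drop = FALSE]
    if (!(row$feature %in% exonic_feats)) next  # gene/transcript handled later
    gr <- genomic_intervals(row$seqname, row$start, row$end, strand)
    pieces <- subtract_intervals(gr, all_proxy)
    for (k in seq_along(pieces)) {
      piece <- row
      piece$start <- BiocGenerics::start(pieces)[k]
      piece$end <- BiocGenerics::end(pieces)[k]
      keep[[length(keep) + 1L]] <- piece
      if (row$feature == "exon" && !is.na(row$transcript_id)) {
        tid <- row$transcript_id
        exon_by_tx[[tid]] <- c(exon_by_tx[[tid]],
                               list(c(piece$start, piece$end)))
      }
    }
  }
  kept <- if (length(keep)) do.call(rbind, keep) else src_rows[0, , drop = FALSE]
  # drop aux rows of transcripts that lost all exons
  live_tx <- names(exon_by_tx)
  kept <- kept[kept$feature == "exon" |
                 (kept$transcript_id %in% live_tx), , drop = FALSE]
  # re-span transcript rows
  tx_rows <- src_rows[src_rows$feature == "transcript", , drop = FALSE]
  for (j in seq_len(nrow(tx_rows))) {
    tid <- tx_rows$transcript_id[j]
    if (!(tid %in% live_tx)) next
    bounds <- do.call(rbind, exon_by_tx[[tid]])
    row <- tx_rows[j, , drop = FALSE]
    row$start <- min(bounds[, 1]); row$end <- max(bounds[, 2])
    kept <- rbind(kept, row)
  }
  # re-span the gene row
  gene_row <- src_rows[src_rows$feature == "gene", , drop = FALSE]
  if (nrow(gene_row) > 0L && length(live_tx) > 0L) {
    bounds <- do.call(rbind, unlist(exon_by_tx, recursive = FALSE))
    gene_row$start <- min(bounds[, 1]); gene_row$end <- max(bounds[, 2])
    kept <- rbind(kept, gene_row[1, , drop = FALSE])
  }
  kept
}

#' Serialize a split plan as a JSON sidecar
#'
#' @param plan A `split_plan` from [split_gene()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Graft a terminal exon onto a gene model
#'
#' Builds a new transcript consisting of a template transcript's exons that
#' lie 5' of a donor exon, plus the donor exon as the new 3'-terminal exon —
#' the way a terminal exon found by cross-species alignment is added to a
#' related genome's gene model whose corresponding isoform is not annotated.
#' Optionally appends a 3'UTR record of a given length immediately 3' of the
#' donor and a stop codon.
#'
#' @param gene A [gene_model()].
#' @param donor_exon Length-1 `GRanges` on the gene's seqname and strand,
#'   3' (strand-aware downstream) of the template's exons and not overlapping
#'   any exon of the gene.
#' @param transcript_id Id for the new transcript (default
#'   `"<gene_id>-grafted"`).
#' @param template Transcript id to take the 5' exons from; default the
#'   transcript with the most exons.
#' @param utr_length Length in bp of a 3'UTR record appended immediately 3' of
#'   the donor exon's 3' boundary (0 = none). The UTR is emitted
#'   non-overlapping with the donor exon.
#' @param stop_codon `"none"` (default), `"inside"` (last 3 bases of the donor
#'   exon) or `"downstream"` (the 3 bases immediately 3' of the donor).
#' @return The gene model with the grafted transcript added.
#' @export
graft_terminal_exon <- function(gene, donor_exon,
                                transcript_id = paste0(gene$gene_id, "-grafted"),
                                template = NULL, utr_length = 0L,
                                stop_codon = c("none", "inside", "downstream")) {
  stop_codon <- match.arg(stop_codon)
  if (!methods::is(donor_exon, "GRanges") || length(donor_exon) != 1L)
    stop("'donor_exon' must be a single GRanges interval")
  if (as.character(GenomeInfoDb::seqnames(donor_exon)) != gene$seqname)
    stop("donor exon is on ", as.character(GenomeInfoDb::seqnames(donor_exon)),
         " but gene ", gene$gene_id, " is on ", gene$seqname)
  dstrand <- as.character(BiocGenerics::strand(donor_exon))
  if (dstrand != "*" && dstrand != gene$strand)
    stop("donor exon strand (", dstrand, ") does not match gene strand (",
         gene$strand, ")")
  donor_exon <- genomic_intervals(gene$seqname,
                                  BiocGenerics::start(donor_exon),
                                  BiocGenerics::end(donor_exon), gene$strand)
  all_ex <- exonic_bases(gene$transcripts)
  if (length(GenomicRanges::intersect(strip_seqinfo(donor_exon), all_ex)) > 0L)
    stop("donor exon overlaps an existing exon of gene ", gene$gene_id)

  if (is.null(template)) {
    n_ex <- vapply(gene$transcripts, function(tx) length(tx$exons), integer(1))
    template <- names(gene$transcripts)[which.max(n_ex)]
  }
  tpl <- gene$transcripts[[template]]
  if (is.null(tpl)) stop("template transcript ", template, " not found")
  if (transcript_id %in% names(gene$transcripts))
    stop("transcript id ", transcript_id, " already exists in gene ", gene$gene_id)

  ds <- BiocGenerics::start(donor_exon)
  de <- BiocGenerics::end(donor_exon)
  if (gene$strand == "+") {
    keep <- tpl$exons[BiocGenerics::end(tpl$exons) < ds]
  } else {
    keep <- tpl$exons[BiocGenerics::start(tpl$exons) > de]
  }
  if (length(keep) == 0L)
    stop("donor exon is not 3' of any exon of template transcript ", template)

  utr3 <- GenomicRanges::GRanges()
  if (utr_length > 0L) {
    utr3 <- if (gene$strand == "+") {
      genomic_intervals(gene$seqname, de + 1L, de + utr_length, "+")
    } else {
      genomic_intervals(gene$seqname, ds - utr_length, ds - 1L, "-")
    }
  }
  stop_gr <- switch(stop_codon,
    none = GenomicRanges::GRanges(),
    inside = if (gene$strand == "+")
      genomic_intervals(gene$seqname, de - 2L, de, "+")
    else genomic_intervals(gene$seqname, ds, ds + 2L, "-"),
    downstream = if (gene$strand == "+")
      genomic_intervals(gene$seqname, de + 1L, de + 3L, "+")
    else genomic_intervals(gene$seqname, ds - 3L, ds - 1L, "-")
  )

  new_tx <- transcript_model(
    transcript_id = transcript_id, gene_id = gene$gene_id,
    seqname = gene$seqname, strand = gene$strand,
    exons = c(strip_seqinfo(keep), strip_seqinfo(donor_exon)),
    utr3 = utr3, stop_codon = stop_gr
  )
  gene$transcripts[[transcript_id]] <- new_tx
  gene
}

#' Genomic span of a transcript model
#'
#' @param tx A `transcript_model`.
#' @return Length-1 `GRanges` from the first to the last exon base.
#' @export
transcript_span <- function(tx) {
  if (length(tx$exons) == 0L) stop("transcript has no exons")
  range(strip_seqinfo(tx$exons))
}
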