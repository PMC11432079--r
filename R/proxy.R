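#' Partition a gene's transcripts into isoform groups
#'
#' Either by an explicit `name -> transcript_ids` specification (the way the
#' THRA1/THRA2 variant lists are given for the THRA locus) or automatically by
#' identical 3'-terminal exon (`auto = TRUE`): transcripts whose terminal
#' exon(s) occupy exactly the same genomic interval(s) form one group.
#' Transcripts not covered by an explicit specification are reported as
#' unassigned; they are excluded from proxies but retained in the shared gene.
#'
#' @param gene A [gene_model()].
#' @param groups Named list, `name -> character vector of transcript_ids`;
#'   `NULL` for automatic grouping.
#' @param auto Group by identical terminal exon (default when `groups` is
#'   `NULL`). Automatic groups are named `<gene_name>.1`, `<gene_name>.2`, ...
#'   in 5'-to-3' order of their terminal boundary.
#' @return An object of class `isoform_partition`: list with `groups` (list of
#'   `isoform_group`: `name`, `transcript_ids`) and `unassigned` (character).
#' @export
partition_transcripts <- function(gene, groups = NULL, auto = is.null(groups)) {
  tx_ids <- names(gene$transcripts)
  if (length(tx_ids) == 0L) stop("gene ", gene$gene_id, " has no transcripts")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("explicit groups must be a named list")
    all_ids <- unlist(groups, use.names = FALSE)
    unknown <- setdiff(all_ids, tx_ids)
    if (length(unknown) > 0L)
      stop("unknown transcript_id(s) in grouping spec: ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(all_ids))
      stop("transcript(s) assigned to more than one group: ",
           paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
    out <- lapply(names(groups), function(nm)
      isoform_group(nm, as.character(groups[[nm]])))
    unassigned <- setdiff(tx_ids, all_ids)
  } else if (auto) {
    keys <- vapply(gene$transcripts, function(tx) {
      te <- terminal_exon(tx)
      paste(BiocGenerics::start(te), BiocGenerics::end(te),
            sep = "-", collapse = ";")
    }, character(1))
    # order groups 5'->3' by terminal boundary
    boundary <- vapply(gene$transcripts, function(tx) {
      te <- terminal_exon(tx)
      if (gene$strand == "+") max(BiocGenerics::end(te))
      else -min(BiocGenerics::start(te))
    }, numeric(1))
    uk <- unique(keys[order(boundary, keys)])
    label <- if (is.na(gene$gene_name)) gene$gene_id else gene$gene_name
    out <- lapply(seq_along(uk), function(i)
      isoform_group(sprintf("%s.%d", label, i), tx_ids[keys == uk[i]]))
    unassigned <- character(0)
  } else {
    stop("either supply explicit 'groups' or set auto = TRUE")
  }
  structure(list(groups = out, unassigned = unassigned),
            class = "isoform_partition")
}

isoform_group <- function(name, transcript_ids) {
  if (length(transcript_ids) == 0L)
    stop("isoform group '", name, "' is empty")
  structure(list(name = name, transcript_ids = transcript_ids),
            class = "isoform_group")
}

#' @export
print.isoform_partition <- function(x, ...) {
  cat(sprintf("<isoform_partition> %d group(s)\n", length(x$groups)))
  for (g in x$groups)
    cat(sprintf("  %s: %s\n", g$name, paste(g$transcript_ids, collapse = ", ")))
  if (length(x$unassigned))
    cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}

#' 3'-terminal region of an isoform group
#'
#' Strand-aware union, over the group's transcripts, of the 3'-most exon(s),
#' the annotated 3'UTR and the stop codon. 10X-style reads pile up in the
#' 3'UTR, so the annotated UTR is part of the countable footprint, not only
#' the exon record.
#'
#' @param group An `isoform_group` (or character vector of transcript ids).
#' @param gene The [gene_model()] the group belongs to.
#' @return Merged `GRanges`.
#' @export
terminal_region <- function(group, gene) {
  ids <- if (inherits(group, "isoform_group")) group$transcript_ids else group
  missing <- setdiff(ids, names(gene$transcripts))
  if (length(missing) > 0L)
    stop("transcript(s) not in gene ", gene$gene_id, ": ",
         paste(missing, collapse = ", "))
  parts <- lapply(gene$transcripts[ids], function(tx) {
    c(strip_seqinfo(terminal_exon(tx)), strip_seqinfo(tx$utr3),
      strip_seqinfo(tx$stop_codon))
  })
  merge_intervals(do.call(c, unname(parts)))
}

#' Distinguishing 3' region (proxy region) of an isoform group
#'
#' The group's merged terminal region minus the merged exonic bases of every
#' transcript outside the group (other groups and unassigned transcripts).
#' This generalizes trimming a read-through terminal exon at the boundary of
#' the last shared exon: bases shared with any other isoform cannot identify
#' the group and are removed.
#'
#' @param group An `isoform_group`.
#' @param gene The [gene_model()].
#' @param partition The `isoform_partition` (used to identify transcripts
#'   outside the group, including unassigned ones).
#' @param min_length Minimum proxy length in bp; shorter results are an error.
#'   Default 100.
#' @param warn_below Emit a warning when the proxy is shorter than this many
#'   bp (default 300; a ~90 bp tag read needs room to land uniquely).
#' @return An object of class `proxy_region`: list with `group_name`,
#'   `intervals` (merged disjoint `GRanges`) and `proxy_length` (bp).
#' @export
distinguishing_region <- function(group, gene, partition,
                                  min_length = 100L, warn_below = 300L) {
  term <- terminal_region(group, gene)
  other_ids <- setdiff(names(gene$transcripts), group$transcript_ids)
  if (length(other_ids) > 0L) {
    other <- exonic_bases(gene$transcripts[other_ids])
    region <- subtract_intervals(term, other)
  } else {
    region <- term
  }
  if (length(region) == 0L || sum(BiocGenerics::width(region)) == 0L) {
    colliders <- collision_groups(term, gene, partition, group$name)
    stop("isoforms of group '", group$name,
         "' are not 3'-distinguishable: terminal region fully shared with ",
         if (length(colliders)) paste0("group(s) ", paste(colliders, collapse = ", "))
         else "other transcripts of the gene")
  }
  len <- sum(BiocGenerics::width(region))
  if (len < min_length)
    stop("proxy region for group '", group$name, "' is only ", len,
         " bp (< min_length = ", min_length, " bp)")
  if (len < warn_below)
    warning("proxy region for group '", group$name, "' is short (", len,
            " bp); tag reads may not land uniquely")
  structure(list(group_name = group$name, intervals = region,
                 proxy_length = len),
            class = "proxy_region")
}

collision_groups <- function(term, gene, partition, self) {
  hits <- character(0)
  for (g in partition$groups) {
    if (g$name == self) next
    bases <- exonic_bases(gene$transcripts[g$transcript_ids])
    if (length(bases) && length(GenomicRanges::intersect(term, bases)) > 0L)
      hits <- c(hits, g$name)
  }
  hits
}

#' @export
print.proxy_region <- function(x, ...) {
  cat(sprintf("<proxy_region> %s: %d interval(s), %d bp\n",
              x$group_name, length(x$intervals), x$proxy_length))
  iv <- x$intervals
  cat(paste0(sprintf("  %s:%s-%s(%s)",
                     as.character(GenomeInfoDb::seqnames(iv)),
                     format(BiocGenerics::start(iv), big.mark = ",", trim = TRUE),
                     format(BiocGenerics::end(iv), big.mark = ",", trim = TRUE),
                     as.character(BiocGenerics::strand(iv))),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Compute proxy regions for every group of a partition
#'
#' Runs [distinguishing_region()] for each group and verifies the global
#' invariants: proxies are pairwise disjoint and share no base with the
#' exonic bases retained by the shared gene.
#'
#' @inheritParams distinguishing_region
#' @return Named list of `proxy_region` objects (one per group).
#' @examples
#' fx <- make_fixture("thra-like")
#' part <- partition_transcripts(fx$gene, auto = TRUE)
#' proxy_regions(fx$gene, part)
#' @export
proxy_regions <- function(gene, partition, min_length = 100L,
                          warn_below = 300L) {
  proxies <- lapply(partition$groups, distinguishing_region, gene = gene,
                    partition = partition, min_length = min_length,
                    warn_below = warn_below)
  names(proxies) <- vapply(partition$groups, `[[`, character(1), "name")
  ivs <- lapply(proxies, `[[`, "intervals")
  all_iv <- do.call(c, unname(lapply(ivs, strip_seqinfo)))
  if (!IRanges::isDisjoint(IRanges::ranges(all_iv)))
    stop("internal error: proxy regions of different groups overlap")
  # proxies must not intersect bases kept by the shared gene
  shared <- subtract_intervals(exonic_bases(gene$transcripts),
                               merge_intervals(all_iv))
  if (length(shared) > 0L &&
      length(GenomicRanges::intersect(merge_intervals(all_iv), shared)) > 0L)
    stop("internal error: proxy regions overlap retained shared exons")
  proxies
}

#' Read an isoform-grouping specification from YAML or JSON
#'
#' Expected keys: `gene_id` (required), `groups` (`name -> [transcript_id]`,
#' optional), `auto` (logical, optional), `min_length` (optional, bp).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `gene_id`, `groups`, `auto`, `min_length`.
#' @export
read_grouping_spec <- function(path) {
  if (!file.exists(path)) stop("grouping spec not found: ", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(spec$gene_id)) stop("grouping spec must name a gene_id")
  groups <- spec$groups
  if (!is.null(groups)) groups <- lapply(groups, as.character)
  list(gene_id = as.character(spec$gene_id),
       groups = groups,
       auto = isTRUE(spec$auto) || is.null(groups),
       min_length = if (is.null(spec$min_length)) 100L else as.integer(spec$min_length))
}

#' Export proxy regions as BED6
#'
#' @param proxies Named list of `proxy_region` objects (see [proxy_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_proxies_bed <- function(proxies, path) {
  grs <- lapply(proxies, function(p) p$intervals)
  nm <- rep(vapply(proxies, `[[`, character(1), "group_name"),
            lengths(grs))
  write_bed6(do.call(c, unname(lapply(grs, strip_seqinfo))), path, names = nm)
}

# Coerce a list of proxy_region objects into one named GRanges whose names
# identify the owning group (several intervals may share a name).
proxies_to_granges <- function(proxies) {
  if (methods::is(proxies, "GRanges")) {
    if (is.null(base::names(proxies)))
      stop("region GRanges must carry names identifying the group")
    return(proxies)
  }
  if (inherits(proxies, "proxy_region")) proxies <- list(proxies)
  grs <- lapply(proxies, function(p) {
    if (!inherits(p, "proxy_region"))
      stop("'regions' must be proxy_region objects or a named GRanges")
    g <- strip_seqinfo(p$intervals)
    base::names(g) <- rep(p$group_name, length(g))
    g
  })
  do.call(c, unname(grs))
}
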