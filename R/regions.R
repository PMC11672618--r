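#' Partition sequences into exonic, intronic and intergenic space
#'
#' Builds, for each sequence, a disjoint interval partition: exon = union of
#' all exon features (exon precedence where isoforms disagree, so one
#' transcript's exon overriding another's intron is exonic); intron = the
#' part of a gene span not covered by exon; intergenic = everything else.
#' Gene spans are `min(start)..max(end)` over a gene's features.  Features
#' extending past the sequence end are clipped with a warning.
#'
#' @param annotation Annotation tibble from [read_gff3()].
#' @param seq_lengths Named vector of sequence lengths in bp.
#' @return A named list (one element per sequence) of lists with `IRanges`
#'   components `exon`, `intron`, `intergenic` and a `genes` tibble
#'   (`gene_id`, `start`, `end`), of class `region_index`.
#' @export
build_region_index <- function(annotation, seq_lengths) {
  stopifnot(!is.null(names(seq_lengths)))
  ann <- tibble::as_tibble(annotation)
  if (nrow(ann) > 0) {
    over <- ann$end > seq_lengths[ann$seq_id]
    over[is.na(over)] <- FALSE
    if (any(over)) {
      warning(sum(over), " feature(s) extend past the sequence end; clipped",
              call. = FALSE)
      ann$end[over] <- as.integer(seq_lengths[ann$seq_id[over]])
    }
  }
  ann <- resolve_gene_ids(ann)
  empty_genes <- tibble::tibble(gene_id = character(), start = integer(),
                                end = integer())
  idx <- lapply(names(seq_lengths), function(sid) {
    len <- as.integer(seq_lengths[[sid]])
    whole <- IRanges::IRanges(1L, len)
    sub <- if (nrow(ann) > 0) ann[ann$seq_id == sid, , drop = FALSE] else ann
    if (nrow(sub) > 0) {
      exons <- sub[sub$feature_type == "exon", , drop = FALSE]
      exon_ir <- IRanges::reduce(IRanges::IRanges(exons$start, exons$end))
      genes <- sub |>
        dplyr::filter(!is.na(.data$gene_id)) |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         .groups = "drop")
    } else {
      exon_ir <- IRanges::IRanges()
      genes <- empty_genes
    }
    gene_ir <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
    intron_ir <- IRanges::setdiff(gene_ir, exon_ir)
    intergenic_ir <- IRanges::setdiff(whole, IRanges::union(gene_ir, exon_ir))
    structure(list(exon = exon_ir, intron = intron_ir,
                   intergenic = intergenic_ir, genes = genes,
                   length_bp = len), class = "region_partition")
  })
  structure(stats::setNames(idx, names(seq_lengths)), class = "region_index")
}

# Attach a gene_id to every feature by walking Parent links
# (exon -> mRNA -> gene); features already of type gene are their own gene.
resolve_gene_ids <- function(ann) {
  if (nrow(ann) == 0) {
    ann$gene_id <- character(0)
    return(ann)
  }
  parent_of <- stats::setNames(ann$parent_id, ann$feature_id)
  type_of <- stats::setNames(ann$feature_type, ann$feature_id)
  find_gene <- function(id, parent) {
    cur_id <- id
    cur_parent <- parent
    for (hop in 1:3) {
      if (!is.na(cur_id) && !is.na(type_of[cur_id]) && type_of[cur_id] == "gene") {
        return(cur_id)
      }
      if (is.na(cur_parent)) {
        # no resolvable gene record: treat the topmost known ancestor as a gene
        return(cur_id)
      }
      nxt <- cur_parent
      cur_id <- nxt
      cur_parent <- if (nxt %in% names(parent_of)) parent_of[[nxt]] else NA_character_
    }
    cur_id
  }
  ann$gene_id <- mapply(find_gene, ann$feature_id, ann$parent_id,
                        USE.NAMES = FALSE)
  ann
}

#' Assign SSR records to genomic regions
#'
#' Classifies each record (standalone locus or compound) as exonic, intronic
#' or intergenic by the category of the base at the record's *start*
#' position — a deterministic single-point rule for records that straddle a
#' boundary.  An alternative majority-overlap rule is available.
#'
#' @param records Record tibble from [merge_compound_ssrs()] (or a locus
#'   tibble from [scan_ssrs()], each locus then being its own record).
#' @param index Region index from [build_region_index()].
#' @param boundary_rule `"start"` (default) or `"majority"` (category with
#'   the largest base overlap; ties exon > intron > intergenic).
#' @return The records tibble with `region` and `gene_id` columns appended
#'   (`gene_id` is the overlapping gene at the classifying position, `NA`
#'   for intergenic records).
#' @export
assign_regions <- function(records, index, boundary_rule = c("start", "majority")) {
  boundary_rule <- match.arg(boundary_rule)
  stopifnot(inherits(index, "region_index"))
  recs <- tibble::as_tibble(records)
  missing_seq <- setdiff(unique(recs$seq_id), names(index))
  if (length(missing_seq) > 0) {
    stop("sequence(s) absent from region index: ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  n <- nrow(recs)
  region <- character(n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    part <- index[[recs$seq_id[i]]]
    if (boundary_rule == "start") {
      q <- IRanges::IRanges(recs$start[i], recs$start[i])
      cat_i <- if (IRanges::countOverlaps(q, part$exon) > 0) "exon"
               else if (IRanges::countOverlaps(q, part$intron) > 0) "intron"
               else "intergenic"
    } else {
      q <- IRanges::IRanges(recs$start[i], recs$end[i])
      ov <- vapply(part[c("exon", "intron", "intergenic")], function(ir) {
        sum(IRanges::width(IRanges::intersect(q, ir)))
      }, numeric(1))
      cat_i <- names(ov)[which.max(ov)]   # which.max ties: first = exon first
    }
    region[i] <- cat_i
    if (cat_i != "intergenic" && nrow(part$genes) > 0) {
      pos <- recs$start[i]
      hit <- part$genes$start <= pos & part$genes$end >= pos
      if (any(hit)) gene[i] <- part$genes$gene_id[which(hit)[1L]]
    }
  }
  recs$region <- region
  recs$gene_id <- gene
  recs
}

#' Tabulate SSR records by repeat type and genomic region
#'
#' Builds the classic type-by-region contingency table: one row per period
#' (`di` .. `hexa`) plus `compound`, columns `exon` / `intergenic` /
#' `intron`, with row totals and overall column percentages computed over
#' the grand total.  Compound records count once (not per member).
#'
#' Accepts either assigned records from [assign_regions()] or a
#' pre-tabulated count data frame with columns `type`, `exon`, `intergenic`,
#' `intron`, so published tables can be fed straight in.
#'
#' @param assignments Assigned records (with `type` and `region` columns) or
#'   a pre-tabulated count data frame.
#' @return A list with `counts` (tibble: `type`, `exon`, `intergenic`,
#'   `intron`, `all`), `region_pct` (named vector of overall region
#'   percentages over the grand total) and `grand_total`.
#' @export
region_distribution <- function(assignments) {
  a <- tibble::as_tibble(assignments)
  if (all(c("exon", "intergenic", "intron") %in% names(a))) {
    counts <- a[c("type", "exon", "intergenic", "intron")]
  } else {
    stopifnot(all(c("type", "region") %in% names(a)))
    counts <- a |>
      dplyr::count(.data$type, .data$region) |>
      tidyr::pivot_wider(names_from = "region", values_from = "n",
                         values_fill = 0L)
    for (col in c("exon", "intergenic", "intron")) {
      if (!col %in% names(counts)) counts[[col]] <- 0L
    }
    counts <- counts[c("type", "exon", "intergenic", "intron")]
    type_order <- c(paste0("p", 2:6), "c")
    counts <- counts[order(match(counts$type, type_order)), ]
  }
  counts$all <- counts$exon + counts$intergenic + counts$intron
  grand <- sum(counts$all)
  region_pct <- 100 * c(exon = sum(counts$exon),
                        intergenic = sum(counts$intergenic),
                        intron = sum(counts$intron)) / grand
  list(counts = counts, region_pct = region_pct, grand_total = grand)
}
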