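#' Tag-level count table
#'
#' The central data container of the package: one row per tag (a transcript
#' isoform defined by its cleavage/polyadenylation site), one count column per
#' sequencing library, and a design mapping libraries to two conditions
#' (condition 1 = resting/normal state, condition 2 = treated/stimulated
#' state) with `r` replicates each.
#'
#' Tags are stored grouped by gene and sorted proximal-to-distal within each
#' gene. Positions are treated as opaque sort keys: with
#' `position_type = "transcript"` (the default) ascending position means
#' proximal (closest to the transcription start) first regardless of strand;
#' with `position_type = "genomic"` the order is strand aware (on the minus
#' strand a larger coordinate is more proximal).
#'
#' @param tags data.frame with columns `tag_id`, `gene_id`, `gene_name`,
#'   `strand` (`"+"` or `"-"`), `position` (numeric sort key), `annotation`.
#' @param counts numeric matrix, rows = tags (in `tags` order), columns =
#'   libraries; non-negative, possibly non-integer after normalization.
#' @param libraries data.frame with columns `library_id`, `condition`
#'   (integer 1 or 2), `replicate` (1..r within condition).
#' @param position_type `"transcript"` or `"genomic"` (see above).
#'
#' @return An object of class `TagCountTable`: a list with elements `tags`,
#'   `counts` (rownames = tag ids, colnames = library ids), `libraries` and
#'   `position_type`.
#' @export
tag_count_table <- function(tags, counts,
                            libraries,
                            position_type = c("transcript", "genomic")) {
  position_type <- match.arg(position_type)
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"

  need <- c("tag_id", "gene_id", "gene_name", "strand", "position", "annotation")
  miss <- setdiff(need, names(tags))
  if (length(miss) > 0L)
    stop("tag metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tags$tag_id))
    stop("duplicate tag_id: ",
         paste(unique(tags$tag_id[duplicated(tags$tag_id)]), collapse = ", "))
  if (nrow(counts) != nrow(tags))
    stop("counts has ", nrow(counts), " rows but there are ", nrow(tags), " tags")
  if (ncol(counts) != nrow(libraries))
    stop("counts has ", ncol(counts), " columns but the design lists ",
         nrow(libraries), " libraries")
  if (anyNA(counts))
    stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count for tag '", tags$tag_id[bad[1L]],
         "' in library '", libraries$library_id[bad[2L]], "'")
  }

  libraries$condition <- .parse_condition(libraries$condition)
  libraries$replicate <- as.integer(libraries$replicate)
  if (length(unique(libraries$condition)) != 2L)
    stop("exactly two conditions required")
  r1 <- sum(libraries$condition == 1L)
  r2 <- sum(libraries$condition == 2L)
  if (r1 != r2)
    stop("both conditions must have the same replicate count (got ",
         r1, " and ", r2, ")")
  if (r1 < 2L)
    stop("at least 2 replicates per condition are required")
  for (j in 1:2) {
    reps <- sort(libraries$replicate[libraries$condition == j])
    if (!identical(reps, seq_len(r1)))
      stop("replicate indices of condition ", j, " must be 1..", r1)
  }

  ord <- .tag_order(tags, position_type)
  tags <- tags[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(tags) <- NULL
  dimnames(counts) <- list(tags$tag_id, libraries$library_id)

  structure(
    list(tags = tags, counts = counts, libraries = libraries,
         position_type = position_type),
    class = "TagCountTable"
  )
}

# condition labels: accept {1,2} or {rest,stim} (case-insensitive)
.parse_condition <- function(x) {
  if (is.numeric(x)) {
    cond <- as.integer(x)
  } else {
    lab <- tolower(trimws(as.character(x)))
    cond <- ifelse(lab %in% c("1", "rest", "ns", "normal"), 1L,
                   ifelse(lab %in% c("2", "stim", "ts", "stimulated", "treated"),
                          2L, NA_integer_))
  }
  if (anyNA(cond) || !all(cond %in% c(1L, 2L)))
    stop("exactly two conditions required (conditions must be 1/rest or 2/stim; ",
         "offending value: '",
         x[which(is.na(cond) | !(cond %in% c(1L, 2L)))[1L]], "')")
  cond
}

# group tags by gene (first-appearance order) and sort proximal -> distal
.tag_order <- function(tags, position_type) {
  gene_rank <- match(tags$gene_id, unique(tags$gene_id))
  pos <- as.numeric(tags$position)
  if (position_type == "genomic") {
    # minus strand: larger genomic coordinate = closer to the TSS = proximal
    pos <- ifelse(tags$strand == "-", -pos, pos)
  }
  order(gene_rank, pos, tags$tag_id)
}

#' @export
print.TagCountTable <- function(x, ...) {
  r <- sum(x$libraries$condition == 1L)
  cat("TagCountTable: ", nrow(x$tags), " tags in ",
      length(unique(x$tags$gene_id)), " genes; ",
      ncol(x$counts), " libraries (", r, " replicates x 2 conditions)\n",
      sep = "")
  invisible(x)
}

#' Number of tags per gene
#'
#' @param t a [tag_count_table()].
#' @return Named integer vector of tag counts (Z_g), in gene order.
#' @export
gene_sizes <- function(t) {
  stopifnot(inherits(t, "TagCountTable"))
  tab <- table(factor(t$tags$gene_id, levels = unique(t$tags$gene_id)))
  stats::setNames(as.integer(tab), names(tab))
}

# library column indices ordered condition 1 replicates 1..r, then condition 2
.lib_index <- function(t) {
  lib <- t$libraries
  r <- sum(lib$condition == 1L)
  idx1 <- order(lib$replicate[lib$condition == 1L])
  idx2 <- order(lib$replicate[lib$condition == 2L])
  list(r = r,
       cond1 = which(lib$condition == 1L)[idx1],
       cond2 = which(lib$condition == 2L)[idx2])
}

#' Read a tag count table and its library design
#'
#' The count file is a comma-separated table with a header row containing the
#' six metadata columns `tagid,geneid,name,strand,pos,annotation` followed by
#' one count column per library. The design file has columns
#' `library_id,condition,replicate` with condition coded `rest`/`stim` or
#' `1`/`2`. Every count column must be mapped by the design and vice versa.
#'
#' @param count_path path to the count CSV.
#' @param design_path path to the design CSV.
#' @param position_type `"transcript"` (default) or `"genomic"`; see
#'   [tag_count_table()].
#' @return A [tag_count_table()].
#' @export
read_tag_table <- function(count_path, design_path,
                           position_type = c("transcript", "genomic")) {
  position_type <- match.arg(position_type)
  raw <- utils::read.csv(count_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- c("tagid", "geneid", "name", "strand", "pos", "annotation")
  miss <- setdiff(meta_cols, names(raw))
  if (length(miss) > 0L)
    stop("count file is missing metadata column(s): ",
         paste(miss, collapse = ", "))
  lib_cols <- setdiff(names(raw), meta_cols)
  if (length(lib_cols) < 2L)
    stop("count file must contain at least two library columns")

  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  need <- c("library_id", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0L)
    stop("design file is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(design$library_id, lib_cols)
  if (length(unknown) > 0L)
    stop("design refers to unknown library column(s): ",
         paste(unknown, collapse = ", "))
  unmapped <- setdiff(lib_cols, design$library_id)
  if (length(unmapped) > 0L)
    stop("count column(s) not mapped by the design: ",
         paste(unmapped, collapse = ", "))

  tags <- data.frame(
    tag_id = as.character(raw$tagid),
    gene_id = as.character(raw$geneid),
    gene_name = as.character(raw$name),
    strand = as.character(raw$strand),
    position = as.numeric(raw$pos),
    annotation = as.character(raw$annotation),
    stringsAsFactors = FALSE
  )
  counts <- as.matrix(raw[, design$library_id, drop = FALSE])
  tag_count_table(tags, counts, design, position_type = position_type)
}

#' Write a tag count table (and optionally its design) to CSV
#'
#' Uses the same dialect as [read_tag_table()]. Counts are printed with
#' `%.17g` so that doubles survive a write/read round trip bit-exact.
#'
#' @param t a [tag_count_table()].
#' @param count_path output path for the count CSV.
#' @param design_path optional output path for the design CSV.
#' @return `count_path`, invisibly.
#' @export
write_tag_table <- function(t, count_path, design_path = NULL) {
  stopifnot(inherits(t, "TagCountTable"))
  header <- paste(c("tagid", "geneid", "name", "strand", "pos", "annotation",
                    t$libraries$library_id), collapse = ",")
  num <- apply(t$counts, 1:2, function(x) sprintf("%.17g", x))
  pos <- sprintf("%.17g", t$tags$position)
  rows <- paste(t$tags$tag_id, t$tags$gene_id, t$tags$gene_name,
                t$tags$strand, pos, t$tags$annotation,
                apply(num, 1L, paste, collapse = ","), sep = ",")
  writeLines(c(header, rows), count_path)
  if (!is.null(design_path)) {
    lab <- ifelse(t$libraries$condition == 1L, "rest", "stim")
    writeLines(c("library_id,condition,replicate",
                 paste(t$libraries$library_id, lab, t$libraries$replicate,
                       sep = ",")),
               design_path)
  }
  invisible(count_path)
}

#' Median-of-ratios library normalization
#'
#' Size factors are estimated with the median-of-ratios method: the reference
#' for each tag is its geometric mean across libraries (computed over tags
#' with all-positive counts), and each library's factor is the median of its
#' count/reference ratios. Factors are then centered so their geometric mean
#' is exactly 1, and each library's counts are divided by its factor.
#' Re-application is a no-op up to numerical tolerance.
#'
#' @param t a [tag_count_table()].
#' @return A list with elements `table` (the normalized [tag_count_table()])
#'   and `size_factors` (named numeric vector, one per library).
#' @export
normalize_libraries <- function(t) {
  stopifnot(inherits(t, "TagCountTable"))
  counts <- t$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no tag has positive counts in every library; ",
         "pre-filter all-zero/low tags before normalization")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)                       # log geometric mean per tag
  sf <- apply(logc, 2L, function(col) exp(stats::median(col - ref)))
  sf <- sf / exp(mean(log(sf)))               # center: geometric mean 1
  out <- t
  out$counts <- sweep(counts, 2L, sf, "/")
  list(table = out, size_factors = stats::setNames(sf, t$libraries$library_id))
}
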