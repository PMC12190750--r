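# Reading and writing modkit-style bedMethyl tables and sample sheets, and
# assembling per-modification count tables keyed by site and sample.

#' Supported modification codes
#'
#' Single-letter / ChEBI-style codes used in bedMethyl column 4:
#' `"a"` (N6-methyladenosine), `"m"` (5-methylcytosine), `"17596"` (inosine)
#' and `"17802"` (pseudouridine).
#'
#' @return Character vector of the four supported codes.
#' @export
dms_mod_codes <- function() c("a", "m", "17596", "17802")

# Canonical per-site identifier used to join tables across samples and lines.
# end is implied (start + 1), so it is not part of the key.
site_id <- function(reference, start, strand, mod_code) {
  paste(reference, start, strand, mod_code, sep = "|")
}

#' Read a modkit-style bedMethyl file
#'
#' Parses the tab-separated bedMethyl dialect emitted by modification-pileup
#' tools: 11 mandatory BED-style columns (chrom, start, end, mod code, score,
#' strand, thickStart, thickEnd, color, valid coverage, percent modified)
#' optionally followed by 7 count columns (n_mod, n_canonical, n_other,
#' n_delete, n_fail, n_diff, n_nocall). Coordinates are 0-based half-open and
#' every record spans exactly one nucleotide.
#'
#' When the count columns are present, `percent_modified` is recomputed from
#' the counts (counts are the primary data; the file's percent column is
#' advisory). When they are absent, counts are reconstructed from the percent
#' column as `n_mod = round(percent/100 * n_valid)` with a warning.
#'
#' @param path Path to a bedMethyl file.
#' @param allowed_mod_codes Modification codes to keep; rows carrying other
#'   codes are skipped and counted in the `n_skipped` attribute.
#' @return A data frame with one row per retained record and columns
#'   `reference`, `start`, `end`, `strand`, `mod_code`, `n_valid`, `n_mod`,
#'   `n_canonical`, `n_other`, `percent_modified` (a fraction in \[0, 1\]).
#'   The number of rows skipped for carrying other codes is attached as
#'   attribute `n_skipped`.
#' @seealso [write_bedmethyl()], [build_count_tables()]
#' @export
read_bedmethyl <- function(path, allowed_mod_codes = dms_mod_codes()) {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_bedmethyl(n_skipped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed bedMethyl row (fewer than 11 columns) at line ",
         which(nf < 11L)[1L])
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  reference <- get(1L)
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  mod_code <- get(4L)
  strand <- get(6L)
  n_valid <- suppressWarnings(as.integer(get(10L)))
  percent <- suppressWarnings(as.numeric(get(11L)))

  bad <- is.na(start) | is.na(end) | is.na(n_valid) | is.na(percent)
  if (any(bad)) {
    stop("malformed bedMethyl row (non-numeric coordinate or count) at line ",
         which(bad)[1L])
  }
  bad <- end != start + 1L
  if (any(bad)) {
    stop("malformed bedMethyl row (end != start + 1) at line ", which(bad)[1L])
  }
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    stop("malformed bedMethyl row (unknown strand) at line ", which(bad)[1L])
  }

  has_counts <- nf >= 13L
  n_mod <- n_canonical <- n_other <- integer(length(lines))
  if (any(has_counts)) {
    idx <- which(has_counts)
    cnt <- function(i) suppressWarnings(as.integer(vapply(fields[idx], `[[`, "", i)))
    n_mod[idx] <- cnt(12L)
    n_canonical[idx] <- cnt(13L)
    n_other[idx] <- if (all(nf[idx] >= 14L)) cnt(14L) else 0L
    bad <- idx[is.na(n_mod[idx]) | is.na(n_canonical[idx]) | is.na(n_other[idx])]
    if (length(bad)) {
      stop("malformed bedMethyl row (non-integer counts) at line ", bad[1L])
    }
  }
  if (any(!has_counts)) {
    idx <- which(!has_counts)
    n_mod[idx] <- as.integer(round(percent[idx] / 100 * n_valid[idx]))
    n_canonical[idx] <- n_valid[idx] - n_mod[idx]
    n_other[idx] <- 0L
    warning(length(idx), " row(s) lacked count columns; n_mod reconstructed ",
            "from the percent column")
  }

  keep <- mod_code %in% allowed_mod_codes
  rec <- data.frame(
    reference = reference[keep],
    start = start[keep],
    end = end[keep],
    strand = strand[keep],
    mod_code = mod_code[keep],
    n_valid = n_valid[keep],
    n_mod = n_mod[keep],
    n_canonical = n_canonical[keep],
    n_other = n_other[keep],
    stringsAsFactors = FALSE
  )
  # counts conservation: modkit defines valid coverage as the sum of the
  # modified, canonical and other-modification calls
  bad <- rec$n_mod + rec$n_canonical + rec$n_other != rec$n_valid
  if (any(bad)) {
    stop("bedMethyl row where n_mod + n_canonical + n_other != n_valid ",
         "at line ", which(keep)[bad][1L])
  }
  rec$percent_modified <- ifelse(rec$n_valid > 0, rec$n_mod / rec$n_valid, 0)
  attr(rec, "n_skipped") <- sum(!keep)
  rec
}

empty_bedmethyl <- function(n_skipped = 0L) {
  rec <- data.frame(
    reference = character(), start = integer(), end = integer(),
    strand = character(), mod_code = character(), n_valid = integer(),
    n_mod = integer(), n_canonical = integer(), n_other = integer(),
    percent_modified = numeric(), stringsAsFactors = FALSE
  )
  attr(rec, "n_skipped") <- n_skipped
  rec
}

#' Write records as a modkit-style bedMethyl file
#'
#' Emits the 18-column dialect accepted by [read_bedmethyl()]; the score
#' column carries the valid coverage (as modkit does), percent is written on
#' the 0-100 scale with two decimals, and records with zero coverage are
#' written with percent 0.00. `read_bedmethyl(write_bedmethyl(x))` reproduces
#' `x` exactly on all integer fields.
#'
#' @param records Data frame as returned by [read_bedmethyl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write bedMethyl file: ", path))
  on.exit(close(con))
  if (nrow(records) == 0L) return(invisible(path))
  pct <- ifelse(records$n_valid > 0, 100 * records$n_mod / records$n_valid, 0)
  out <- paste(
    records$reference, records$start, records$end, records$mod_code,
    records$n_valid, records$strand, records$start, records$end, "255,0,0",
    records$n_valid, sprintf("%.2f", pct),
    records$n_mod, records$n_canonical, records$n_other, 0L, 0L, 0L, 0L,
    sep = "\t"
  )
  writeLines(out, con)
  invisible(path)
}

#' Read an experiment sample sheet
#'
#' The sample sheet is a tab-separated file with header columns `sample_id`,
#' `cell_line`, `condition` (`low`/`high`), `material` (`native`/`IVT`),
#' `replicate` and `path` (per-sample bedMethyl file). Relative paths are
#' resolved against the sheet's own directory.
#'
#' @param path Path to the TSV sample sheet.
#' @return Validated data frame of samples.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path) & !file.exists(sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "cell_line", "condition", "material", "replicate", "path")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet has duplicated sample_id values")
  if (!all(sheet$condition %in% c("low", "high")))
    stop("sample sheet condition must be 'low' or 'high'")
  if (!all(sheet$material %in% c("native", "IVT")))
    stop("sample sheet material must be 'native' or 'IVT'")
  invisible(sheet)
}

#' Assemble per-modification count tables from a sample sheet
#'
#' Reads every bedMethyl file referenced in the sheet and builds, per
#' modification code and per material (native / IVT), a dense site-by-sample
#' count table. A site observed in any sample appears in the table; samples
#' without a record at that site contribute (0, 0) — i.e. no coverage.
#'
#' @param sheet Sample sheet data frame (see [read_sample_sheet()]).
#' @param mod_codes Modification codes to tabulate.
#' @return Named list (one element per modification code), each a list with
#'   components `native` and `ivt` holding `site_count_table` objects (or
#'   `NULL` when the sheet has no samples of that material).
#' @export
build_count_tables <- function(sheet, mod_codes = dms_mod_codes()) {
  validate_sample_sheet(sheet)
  recs <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    r <- read_bedmethyl(sheet$path[i], allowed_mod_codes = mod_codes)
    if (nrow(r)) r$sample_id <- sheet$sample_id[i]
    recs[[i]] <- r
  }
  all_rec <- do.call(rbind, recs[vapply(recs, nrow, 0L) > 0])
  out <- list()
  for (mc in mod_codes) {
    sub <- if (is.null(all_rec)) NULL else all_rec[all_rec$mod_code == mc, , drop = FALSE]
    out[[mc]] <- list(
      native = make_count_table(sub, sheet[sheet$material == "native", , drop = FALSE], mc),
      ivt = make_count_table(sub, sheet[sheet$material == "IVT", , drop = FALSE], mc)
    )
  }
  out
}

# Dense (sites x samples) matrices of modified / canonical counts for one
# modification code and one material group.
make_count_table <- function(records, samples, mod_code) {
  if (nrow(samples) == 0L) return(NULL)
  if (!is.null(records)) {
    records <- records[records$sample_id %in% samples$sample_id, , drop = FALSE]
  }
  if (is.null(records) || nrow(records) == 0L) {
    sites <- data.frame(reference = character(), start = integer(),
                        end = integer(), strand = character(),
                        mod_code = character(), stringsAsFactors = FALSE)
    ids <- character()
  } else {
    sid <- site_id(records$reference, records$start, records$strand, records$mod_code)
    dup <- duplicated(paste(sid, records$sample_id))
    if (any(dup)) {
      stop("duplicate (site, sample) record: ", sid[dup][1L], " in sample ",
           records$sample_id[dup][1L])
    }
    first <- !duplicated(sid)
    sites <- records[first, c("reference", "start", "end", "strand", "mod_code"),
                     drop = FALSE]
    o <- order(sites$reference, sites$start, sites$strand)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    ids <- site_id(sites$reference, sites$start, sites$strand, sites$mod_code)
    records$.site <- match(sid, ids)
    records$.samp <- match(records$sample_id, samples$sample_id)
  }
  n_mod <- matrix(0L, nrow = length(ids), ncol = nrow(samples),
                  dimnames = list(ids, samples$sample_id))
  n_canonical <- n_mod
  if (length(ids) && nrow(records)) {
    n_mod[cbind(records$.site, records$.samp)] <- records$n_mod
    n_canonical[cbind(records$.site, records$.samp)] <- records$n_canonical
  }
  structure(
    list(mod_code = mod_code, sites = sites, site_ids = ids,
         samples = samples, n_mod = n_mod, n_canonical = n_canonical),
    class = "site_count_table"
  )
}

#' @export
print.site_count_table <- function(x, ...) {
  cat("site_count_table: mod code '", x$mod_code, "', ",
      length(x$site_ids), " sites x ", nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

# Restrict a count table to a subset of samples (by sample_id).
subset_table_samples <- function(table, sample_ids) {
  keep <- table$samples$sample_id %in% sample_ids
  table$samples <- table$samples[keep, , drop = FALSE]
  table$n_mod <- table$n_mod[, keep, drop = FALSE]
  table$n_canonical <- table$n_canonical[, keep, drop = FALSE]
  table
}

#' Read a transcript-to-gene annotation map
#'
#' @param path TSV with columns `transcript_id`, `gene_id` and optionally
#'   `gene_name`.
#' @return Data frame mapping transcript identifiers to genes.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(gm)))
    stop("gene map must have columns transcript_id and gene_id")
  gm
}

#' Read gene sets for enrichment testing
#'
#' @param path TSV with columns `set_name` and `gene_id`, one gene per row.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gene_sets <- function(path) {
  gs <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene_id") %in% names(gs)))
    stop("gene set file must have columns set_name and gene_id")
  split(gs$gene_id, gs$set_name)
}
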