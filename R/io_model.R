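#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain containers.
#
# All containers are lightweight S3 wrappers around base matrices and data
# frames, validated at construction.  Genomic coordinates are 0-based,
# half-open throughout: a probe at pos == start is inside a region, a probe
# at pos == end is not.  Chromosome names are compared as exact strings.
# ---------------------------------------------------------------------------

#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a numeric matrix of methylation fractions in \[0, 1\]
#' with unique rownames (probe or region identifiers, "units") and unique
#' colnames (sample identifiers).  Missing values are allowed and are encoded
#' as `NA`, never as 0 (0 is a legal methylation value).
#'
#' @param values numeric matrix with rownames (unit ids) and colnames
#'   (sample ids).
#' @return the validated matrix with class `beta_matrix`.
#' @export
beta_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !(nrow(values) == 0))
    stop("beta values must be numeric")
  if (is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values))))
    stop("beta_matrix requires unit ids (rownames) and sample ids (colnames)")
  storage.mode(values) <- "double"
  if (anyDuplicated(rownames(values)))
    stop("duplicate unit ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value outside [0,1] at unit '%s', sample '%s' (%g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  }
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

#' Construct an M-value matrix
#'
#' M-values are the log2 ratio of methylated to unmethylated signal,
#' `log2(beta / (1 - beta))`.  Values must be finite (betas are clipped away
#' from 0/1 before conversion); `NA` is allowed and mirrors missing betas.
#'
#' @param values numeric matrix with rownames and colnames.
#' @return matrix with class `m_matrix`.
#' @export
m_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("M values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("m_matrix requires unit ids (rownames) and sample ids (colnames)")
  if (any(!is.na(values) & !is.finite(values)))
    stop("M values must be finite (clip betas before conversion)")
  structure(values, class = c("m_matrix", "matrix", "array"))
}

#' Construct a probe manifest
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos` (0-based),
#'   `snp_overlap` (logical), `sex_chrom` (logical).
#' @return data.frame with class `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  req <- c("probe_id", "chrom", "pos", "snp_overlap", "sex_chrom")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$snp_overlap <- as.logical(df$snp_overlap)
  df$sex_chrom <- as.logical(df$sex_chrom)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in manifest")
  if (any(df$pos < 0)) stop("manifest positions must be >= 0")
  structure(df, class = c("probe_manifest", "data.frame"))
}

#' Construct a region set
#'
#' Regions are named, 0-based half-open genomic intervals carrying optional
#' imprinted-DMR metadata: `dmr_class` in \{germline, secondary, none\} and
#' `parental_origin` in \{maternal, paternal, none\}.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name` and
#'   optionally `dmr_class`, `parental_origin`.
#' @return data.frame with class `region_set`.
#' @export
region_set <- function(df) {
  req <- c("chrom", "start", "end", "name")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("region set missing columns: ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- as.character(df$name)
  if (is.null(df$dmr_class)) df$dmr_class <- "none"
  if (is.null(df$parental_origin)) df$parental_origin <- "none"
  df$dmr_class[is.na(df$dmr_class) | df$dmr_class == ""] <- "none"
  df$parental_origin[is.na(df$parental_origin) |
                       df$parental_origin == ""] <- "none"
  bad_class <- setdiff(unique(df$dmr_class),
                       c("germline", "secondary", "none"))
  if (length(bad_class) > 0)
    stop("unknown dmr_class: ", paste(bad_class, collapse = ", "))
  bad_po <- setdiff(unique(df$parental_origin),
                    c("maternal", "paternal", "none"))
  if (length(bad_po) > 0)
    stop("unknown parental_origin: ", paste(bad_po, collapse = ", "))
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1]
    stop(sprintf("region '%s' has start >= end (%d >= %d)",
                 df$name[i], df$start[i], df$end[i]))
  }
  if (anyDuplicated(df$name))
    stop("duplicate region names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"))
}

#' Construct a sample sheet
#'
#' Encodes the study design: a panel of `control` samples, `patient`
#' samples, and `corrected` clones each linked to its parent patient via
#' `parent_patient`.  `cell_type` is one of iPSC, fibroblast, blood, hESC.
#'
#' @param df data.frame with columns `sample_id`, `role`, `cell_type` and
#'   optionally `parent_patient`.
#' @return data.frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "role", "cell_type")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$role <- as.character(df$role)
  df$cell_type <- as.character(df$cell_type)
  if (is.null(df$parent_patient)) df$parent_patient <- NA_character_
  df$parent_patient <- as.character(df$parent_patient)
  df$parent_patient[df$parent_patient %in% c("", "none", "NA")] <-
    NA_character_
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  bad_role <- setdiff(unique(df$role), c("control", "patient", "corrected"))
  if (length(bad_role) > 0)
    stop("unknown role: ", paste(bad_role, collapse = ", "))
  bad_ct <- setdiff(unique(df$cell_type),
                    c("iPSC", "fibroblast", "blood", "hESC"))
  if (length(bad_ct) > 0)
    stop("unknown cell_type: ", paste(bad_ct, collapse = ", "))
  corr <- df$role == "corrected"
  if (any(corr & is.na(df$parent_patient)))
    stop("corrected sample(s) without parent_patient: ",
         paste(df$sample_id[corr & is.na(df$parent_patient)],
               collapse = ", "))
  patients <- df$sample_id[df$role == "patient"]
  orphan <- corr & !is.na(df$parent_patient) &
    !(df$parent_patient %in% patients)
  if (any(orphan))
    stop("parent_patient does not name a patient sample: ",
         paste(df$parent_patient[orphan], collapse = ", "))
  if (sum(df$role == "control") < 2)
    warning("fewer than 2 control samples: reference computation will fail")
  rownames(df) <- NULL
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Control sample ids from a sample sheet
#'
#' @param sheet a [sample_sheet()].
#' @param cell_type optional cell type restriction (e.g. `"iPSC"` to use only
#'   the iPSC control panel when the sheet also carries fibroblast or blood
#'   controls).
#' @return character vector of sample ids.
#' @export
control_ids <- function(sheet, cell_type = NULL) {
  keep <- sheet$role == "control"
  if (!is.null(cell_type)) keep <- keep & sheet$cell_type %in% cell_type
  sheet$sample_id[keep]
}

#' @rdname control_ids
#' @export
patient_ids <- function(sheet, cell_type = NULL) {
  keep <- sheet$role == "patient"
  if (!is.null(cell_type)) keep <- keep & sheet$cell_type %in% cell_type
  sheet$sample_id[keep]
}

#' Corrected clones of a given patient
#'
#' @param sheet a [sample_sheet()].
#' @param patient patient sample id.
#' @return character vector of corrected-clone sample ids.
#' @export
clones_of <- function(sheet, patient) {
  sheet$sample_id[sheet$role == "corrected" &
                    !is.na(sheet$parent_patient) &
                    sheet$parent_patient == patient]
}

#' Construct a ChIP count table
#'
#' Long-format per-region ChIP read counts: one row per (region, condition,
#' replicate) with IP and input read counts and their library depths.
#'
#' @param df data.frame with columns `region`, `condition`, `replicate`,
#'   `ip_count`, `input_count`, `ip_depth`, `input_depth`.
#' @return data.frame with class `chip_count_table`.
#' @export
chip_count_table <- function(df) {
  req <- c("region", "condition", "replicate", "ip_count", "input_count",
           "ip_depth", "input_depth")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("chip count table missing columns: ", paste(miss, collapse = ", "))
  for (col in c("ip_count", "input_count", "ip_depth", "input_depth"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$ip_depth <= 0) || any(df$input_depth <= 0))
    stop("library depths must be positive")
  if (any(df$ip_count < 0) || any(df$input_count < 0))
    stop("read counts must be non-negative")
  if (any(df$ip_count > df$ip_depth) || any(df$input_count > df$input_depth))
    stop("read counts cannot exceed library depth")
  rownames(df) <- NULL
  structure(df, class = c("chip_count_table", "data.frame"))
}

# ---------------------------------------------------------------------------
# Readers / writers.  All files are plain TSV.
# ---------------------------------------------------------------------------

read_tsv_checked <- function(path, what, header = TRUE, ...) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE, ...),
    error = function(e) stop("failed to parse ", what, " (", path, "): ",
                             conditionMessage(e)))
  if (nrow(df) == 0) stop(what, ": no data rows in ", path)
  df
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds unit
#' (probe/region) ids; remaining cells are decimals in \[0, 1\] or `NA`.
#'
#' @param path file path.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv_checked(path, "beta matrix")
  if (ncol(df) < 2) stop("beta matrix needs at least one sample column")
  units <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- units
  beta_matrix(vals)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with enough digits to round-trip to at least 6
#' decimal places; axis order is preserved.
#'
#' @param beta a [beta_matrix()] (or m_matrix).
#' @param path output file path.
#' @param id_col name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, id_col = "unit_id") {
  df <- data.frame(rownames(beta), format(unclass(beta), digits = 9,
                                          trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic regions from a BED-like TSV
#'
#' Columns: chrom, start, end, name, and optionally dmr_class
#' (germline/secondary/none) and parental_origin (maternal/paternal/none).
#' Coordinates are taken as 0-based half-open, as in BED.  A header line is
#' auto-detected (a non-numeric value in column 2).
#'
#' @param path file path.
#' @return a [region_set()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("regions file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1 &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- read_tsv_checked(path, "regions", header = has_header)
  if (!has_header) {
    cn <- c("chrom", "start", "end", "name", "dmr_class", "parental_origin")
    names(df) <- cn[seq_len(min(ncol(df), length(cn)))]
  }
  region_set(df)
}

#' Write regions to a BED-like TSV (with header)
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest from TSV
#'
#' Columns: probe_id, chrom, pos (0-based), snp_overlap, sex_chrom.
#'
#' @param path file path.
#' @return a [probe_manifest()].
#' @export
read_manifest <- function(path) {
  probe_manifest(read_tsv_checked(path, "probe manifest"))
}

#' Write a probe manifest to TSV
#' @param manifest a [probe_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Required columns: sample_id, role (control/patient/corrected),
#' cell_type (iPSC/fibroblast/blood/hESC); optional parent_patient
#' (required for corrected samples).
#'
#' @param path file path.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read_tsv_checked(path, "sample sheet"))
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  df <- as.data.frame(sheet)
  df$parent_patient[is.na(df$parent_patient)] <- "none"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format ChIP count table from TSV
#'
#' Columns: region, condition, replicate, ip_count, input_count, ip_depth,
#' input_depth.
#'
#' @param path file path.
#' @return a [chip_count_table()].
#' @export
read_chip_counts <- function(path) {
  chip_count_table(read_tsv_checked(path, "chip counts"))
}

#' Write a ChIP count table to TSV
#' @param counts a [chip_count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chip_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probes contained in each region
#'
#' Containment uses the 0-based half-open convention: `start <= pos < end`
#' with exact chromosome-string match.
#'
#' @param regions a [region_set()].
#' @param manifest a [probe_manifest()].
#' @return named list, one character vector of probe ids per region name.
#' @export
probes_in_regions <- function(regions, manifest) {
  out <- vector("list", nrow(regions))
  names(out) <- regions$name
  for (i in seq_len(nrow(regions))) {
    hit <- manifest$chrom == regions$chrom[i] &
      manifest$pos >= regions$start[i] & manifest$pos < regions$end[i]
    out[[i]] <- manifest$probe_id[hit]
  }
  out
}
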