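## Table and image I/O. Tables are UTF-8 CSV (comma) except intensity
## matrices, which follow the MaxQuant tab-separated convention. Channel
## stacks are multi-page 32-bit float TIFFs; because the TIFF float range
## is [0, 1], each page is scaled by its maximum and the channel name and
## scale factor are stored in a plain-text sidecar (`<path>.channels.csv`).

WELL_REGEX <- "^[A-P](0[1-9]|1[0-9]|2[0-4])$"
WELL_ROLES <- c("sample", "neg_ctrl", "pos_ctrl", "death_ctrl", "empty")

#' Read screen well records from plate-map (and optional values) CSV
#'
#' The plate map carries one row per well: `plate_id`, `well` (384-format
#' labels `A01`..`P24`), `role`, `gene_id`, `sirna_id`, `seed`. Well values
#' (`value`, optionally `n_cells`) may be columns of the same file or come
#' from a second CSV keyed by `plate_id` + `well`.
#'
#' @param plates_path plate-map CSV path.
#' @param values_path optional per-well values CSV path.
#' @return data.frame of validated well records.
#' @export
read_plate_tables <- function(plates_path, values_path = NULL) {
  pm <- utils::read.csv(plates_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("plate_id", "well", "role", "gene_id", "sirna_id", "seed")
  missing_cols <- setdiff(need, names(pm))
  if (length(missing_cols))
    stop("plate map is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_well <- !grepl(WELL_REGEX, pm$well)
  if (any(bad_well))
    stop("invalid well label(s): ",
         paste(utils::head(unique(pm$well[bad_well]), 3), collapse = ", "))
  bad_role <- !pm$role %in% WELL_ROLES
  if (any(bad_role))
    stop("invalid role(s): ",
         paste(utils::head(unique(pm$role[bad_role]), 3), collapse = ", "))
  key <- paste(pm$plate_id, pm$well)
  if (anyDuplicated(key))
    stop("duplicated plate/well: ", key[duplicated(key)][1])
  is_sample <- pm$role == "sample"
  empty_str <- function(x) is.na(x) | x == ""
  if (any(is_sample & (empty_str(pm$gene_id) | empty_str(pm$sirna_id) |
                       empty_str(pm$seed))))
    stop("sample wells must carry gene_id, sirna_id and seed")
  pm$gene_id[empty_str(pm$gene_id)] <- NA_character_
  pm$sirna_id[empty_str(pm$sirna_id)] <- NA_character_
  pm$seed[empty_str(pm$seed)] <- NA_character_

  if (!is.null(values_path)) {
    vv <- utils::read.csv(values_path, stringsAsFactors = FALSE)
    vneed <- c("plate_id", "well", "value")
    if (!all(vneed %in% names(vv)))
      stop("values table is missing column(s): ",
           paste(setdiff(vneed, names(vv)), collapse = ", "))
    m <- match(key, paste(vv$plate_id, vv$well))
    if (anyNA(m))
      stop("no value for well ", key[which(is.na(m))[1]])
    pm$value <- as.numeric(vv$value[m])
    if ("n_cells" %in% names(vv)) pm$n_cells <- as.integer(vv$n_cells[m])
  } else if ("value" %in% names(pm)) {
    pm$value <- as.numeric(pm$value)
    if ("n_cells" %in% names(pm)) pm$n_cells <- as.integer(pm$n_cells)
  }
  if ("value" %in% names(pm) &&
      any(!is.na(pm$value) & pm$value <= 0 & pm$role != "empty"))
    stop("well values must be > 0")
  pm
}

#' Write well records to CSV
#' @param wells data.frame of well records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_tables <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a proteinGroups-style log2 intensity TSV
#'
#' Expects a tab-separated table whose first column holds protein
#' identifiers and remaining columns per-sample intensities, plus a sample
#' metadata TSV (`sample`, `condition`, ...). Contaminant (`CON__`) and
#' reverse-database (`REV__`) rows are dropped on load; zero intensities
#' are treated as missing under the default MaxQuant convention.
#'
#' @param path intensity TSV path.
#' @param meta_path sample metadata TSV path.
#' @param zero_as_missing treat 0 as a missing marker (default `TRUE`).
#' @param log2_transform take log2 of the intensities on load (set when the
#'   file holds raw LFQ intensities rather than log2 values).
#' @return an [intensity_matrix()]; attribute `n_dropped` counts removed
#'   contaminant/reverse rows.
#' @export
read_intensity_tsv <- function(path, meta_path, zero_as_missing = TRUE,
                               log2_transform = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed intensity table: ", path)
  ids <- as.character(raw[[1]])
  drop <- grepl("^(CON__|REV__)", ids)
  n_dropped <- sum(drop)
  raw <- raw[!drop, , drop = FALSE]
  ids <- ids[!drop]
  if (anyDuplicated(ids)) stop("duplicated protein identifiers")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2,
                                              as.numeric))) &
                 !is.na(as.matrix(raw[, -1, drop = FALSE])),
                 arr.ind = TRUE)
    stop("non-numeric intensity at row ", ids[bad[1, 1]], ", column '",
         colnames(raw)[-1][bad[1, 2]], "'")
  }
  rownames(vals) <- ids
  if (zero_as_missing) vals[vals == 0] <- NA_real_
  if (log2_transform) vals <- log2(vals)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  out <- intensity_matrix(vals, meta)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write an intensity matrix (and its metadata) as TSV
#' @param mat an [intensity_matrix()].
#' @param path intensity TSV path; metadata is written next to it as
#'   `<path base>.samples.tsv`.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "intensity_matrix"))
  df <- data.frame(protein = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "0")
  meta_path <- paste0(sub("\\.tsv$", "", path), ".samples.tsv")
  utils::write.table(mat$meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a channel stack as a multi-page TIFF
#'
#' One 32-bit float page per channel. Channel names and per-page scale
#' factors (pages are scaled into the TIFF float range `[0, 1]`) go to a
#' sidecar `<path>.channels.csv`.
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  scale <- vapply(stack, function(p) max(p, 1e-12), numeric(1))
  pages <- lapply(seq_along(stack), function(i) stack[[i]] / scale[i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(channel = names(stack),
                              page = seq_along(stack), scale = scale),
                   paste0(path, ".channels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF into a channel stack
#'
#' Uses the sidecar written by [write_channel_tiff()] when present;
#' otherwise `channels` must map channel names to page numbers (and the
#' intensities are taken as stored).
#'
#' @param path TIFF path.
#' @param channels optional named integer vector, e.g.
#'   `c(DAPI = 1, YFP = 2, EdU = 3)`.
#' @return a [channel_stack()].
#' @export
read_channel_tiff <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".channels.csv")
  if (file.exists(sidecar)) {
    sc <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    planes <- lapply(seq_len(nrow(sc)), function(i)
      pages[[sc$page[i]]] * sc$scale[i])
    names(planes) <- sc$channel
  } else {
    if (is.null(channels) || is.null(names(channels)))
      stop("no channel sidecar found; supply a named `channels` mapping")
    planes <- lapply(channels, function(p) pages[[p]])
    names(planes) <- names(channels)
  }
  channel_stack(planes)
}
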