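WELL_ROLES <- c("library", "neg_ctrl", "gfp_ctrl", "death_ctrl", "empty")
WELL_TREATMENTS <- c("stress", "vehicle", "none")

#' Generate a multi-plate, multi-replicate screen layout
#'
#' Lays out a library of gene knockdowns and per-plate control wells on
#' 384-well-convention plates (rows A..P, columns 1..24 by default) and
#' replicates the arrangement across biological replicates, mirroring an
#' arrayed siRNA library that is physically identical between replicates.
#'
#' Controls occupy the first plate column (overflowing into the last);
#' library genes fill the remaining wells in row-major order after a seeded
#' shuffle of gene order. Negative-control wells alternate between stress
#' and vehicle treatment so every plate carries both arms of the assay
#' window; all other wells are stress-treated. Unused library wells are
#' emitted with role `"empty"` so the plate map always covers the full plate.
#'
#' @param n_library_genes Number of library genes (may be 0).
#' @param n_plates Number of plates per replicate.
#' @param n_replicates Number of biological replicates (>= 1).
#' @param controls_per_plate Named counts of control wells per plate; names
#'   from `neg_ctrl`, `gfp_ctrl`, `death_ctrl`.
#' @param plate_rows,plate_cols Plate format (default 16 x 24 = 384).
#' @param gene_ids Optional character vector of gene identifiers; defaults to
#'   `GENE0001 ...`.
#' @param seed Integer seed for the gene-order shuffle (deterministic layout).
#' @return A `plate_layout`: a data.frame with columns `plate_id`,
#'   `replicate_id`, `well_id`, `gene_id`, `role`, `treatment`, one row per
#'   (replicate, plate, well).
#' @examples
#' lay <- generate_plate_layout(10, 1, 2, plate_rows = 4, plate_cols = 6,
#'                              controls_per_plate = c(neg_ctrl = 4,
#'                                                     death_ctrl = 2),
#'                              seed = 1)
#' table(lay$role) / 2  # per replicate
#' @export
generate_plate_layout <- function(n_library_genes,
                                  n_plates = 1,
                                  n_replicates = 3,
                                  controls_per_plate = c(neg_ctrl = 8,
                                                         gfp_ctrl = 4,
                                                         death_ctrl = 4),
                                  plate_rows = 16,
                                  plate_cols = 24,
                                  gene_ids = NULL,
                                  seed = 1L) {
  stopifnot(n_library_genes >= 0, n_plates >= 1, n_replicates >= 1,
            plate_rows >= 1, plate_rows <= 26, plate_cols >= 1)
  bad <- setdiff(names(controls_per_plate),
                 c("neg_ctrl", "gfp_ctrl", "death_ctrl"))
  if (length(bad))
    stop("unknown control role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  n_controls <- sum(controls_per_plate)
  if (n_controls > 2 * plate_rows)
    stop(sprintf(
      "cannot place %d control wells in the 2 reserved columns (%d slots)",
      n_controls, 2 * plate_rows), call. = FALSE)

  wells_per_plate <- plate_rows * plate_cols
  lib_capacity <- n_plates * (wells_per_plate - n_controls)
  if (n_library_genes > lib_capacity)
    stop(sprintf(
      "library of %d genes exceeds capacity of %d library wells (%d plates); short by %d wells",
      n_library_genes, lib_capacity, n_plates,
      n_library_genes - lib_capacity), call. = FALSE)

  if (is.null(gene_ids)) {
    gene_ids <- sprintf("GENE%04d", seq_len(n_library_genes))
  } else {
    stopifnot(length(gene_ids) == n_library_genes,
              !anyDuplicated(gene_ids))
    gene_ids <- as.character(gene_ids)
  }
  if (n_library_genes > 1) {
    gene_ids <- withr::with_seed(as.integer(seed), sample(gene_ids))
  }

  well_id <- function(r, c) sprintf("%s%02d", LETTERS[r], c)
  # reserved control slots: first column top-down, then last column
  ctrl_slots <- rbind(cbind(seq_len(plate_rows), 1L),
                      if (plate_cols > 1) cbind(seq_len(plate_rows),
                                                plate_cols))
  ctrl_slots <- ctrl_slots[seq_len(n_controls), , drop = FALSE]
  ctrl_roles <- character(0)
  ctrl_treat <- character(0)
  for (role in c("neg_ctrl", "gfp_ctrl", "death_ctrl")) {
    k <- controls_per_plate[role]
    if (is.na(k) || k == 0) next
    ctrl_roles <- c(ctrl_roles, rep(role, k))
    ctrl_treat <- c(ctrl_treat, if (role == "neg_ctrl") {
      rep(c("stress", "vehicle"), length.out = k)
    } else rep("stress", k))
  }

  all_rc <- cbind(rep(seq_len(plate_rows), each = plate_cols),
                  rep(seq_len(plate_cols), times = plate_rows))
  ctrl_key <- paste(ctrl_slots[, 1], ctrl_slots[, 2])
  lib_rc <- all_rc[!(paste(all_rc[, 1], all_rc[, 2]) %in% ctrl_key), ,
                   drop = FALSE]

  plates <- vector("list", n_plates)
  g0 <- 0L
  for (p in seq_len(n_plates)) {
    n_here <- min(n_library_genes - g0, nrow(lib_rc))
    lib_gene <- c(if (n_here > 0) gene_ids[g0 + seq_len(n_here)],
                  rep(NA_character_, nrow(lib_rc) - n_here))
    g0 <- g0 + n_here
    plates[[p]] <- data.frame(
      plate_id = sprintf("P%d", p),
      well_id = c(well_id(ctrl_slots[, 1], ctrl_slots[, 2]),
                  well_id(lib_rc[, 1], lib_rc[, 2])),
      gene_id = c(ctrl_roles, lib_gene),
      role = c(ctrl_roles,
               ifelse(is.na(lib_gene), "empty", "library")),
      treatment = c(ctrl_treat,
                    ifelse(is.na(lib_gene), "none", "stress")),
      stringsAsFactors = FALSE
    )
  }
  one_rep <- do.call(rbind, plates)
  layout <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    cbind(data.frame(replicate_id = sprintf("R%d", r),
                     stringsAsFactors = FALSE),
          one_rep)
  }))
  layout <- layout[, c("plate_id", "replicate_id", "well_id", "gene_id",
                       "role", "treatment")]
  rownames(layout) <- NULL
  attr(layout, "plate_rows") <- plate_rows
  attr(layout, "plate_cols") <- plate_cols
  class(layout) <- c("plate_layout", "data.frame")
  validate_plate_layout(layout)
  layout
}

# Closed-vocabulary and uniqueness checks shared by the generator and the
# plate-map reader; `where` labels error messages with row numbers from the
# source file when reading.
validate_plate_layout <- function(layout, where = NULL) {
  need <- c("plate_id", "replicate_id", "well_id", "gene_id", "role",
            "treatment")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rowtag <- function(i) {
    if (is.null(where)) sprintf("row %d", i) else
      sprintf("%s line %d", where, i + 1L)  # +1 for the header line
  }
  bad <- which(!(layout$role %in% WELL_ROLES))
  if (length(bad))
    stop(sprintf("unknown role '%s' (%s); allowed: %s", layout$role[bad[1]],
                 rowtag(bad[1]), paste(WELL_ROLES, collapse = ", ")),
         call. = FALSE)
  bad <- which(!(layout$treatment %in% WELL_TREATMENTS))
  if (length(bad))
    stop(sprintf("unknown treatment '%s' (%s); allowed: %s",
                 layout$treatment[bad[1]], rowtag(bad[1]),
                 paste(WELL_TREATMENTS, collapse = ", ")), call. = FALSE)
  bad <- which((layout$treatment == "none") != (layout$role == "empty"))
  if (length(bad))
    stop(sprintf("treatment 'none' is reserved for empty wells (%s)",
                 rowtag(bad[1])), call. = FALSE)
  bad <- which(!grepl("^[A-Z][0-9]{2}$", layout$well_id))
  if (length(bad))
    stop(sprintf("malformed well id '%s' (%s); expected e.g. A01..P24",
                 layout$well_id[bad[1]], rowtag(bad[1])), call. = FALSE)
  key <- paste(layout$plate_id, layout$replicate_id, layout$well_id)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (plate, replicate, well) = (%s) at %s",
                 gsub(" ", ", ", key[dup[1]]), rowtag(dup[1])),
         call. = FALSE)
  invisible(layout)
}
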