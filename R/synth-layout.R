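#' Build a multi-plate siRNA library layout
#'
#' Allocates `n_genes` x `oligos_per_gene` library wells (one well per
#' (gene, oligo) pair) across the minimum number of plates of the requested
#' format, reserving `controls_per_plate` wells on every plate for negative,
#' lethal-transfection and LMNA positive controls. The gene/oligo-to-well map
#' is a seeded random permutation, so the layout is deterministic given the
#' seed. Unused library-capacity wells are marked `empty`.
#'
#' The default format is a 384-well plate (16 rows x 24 columns, wells
#' `A01`..`P24`). With 867 genes and 3 oligos per gene this yields the 2601
#' library wells of a full screen replicate.
#'
#' @param n_genes number of genes in the library.
#' @param oligos_per_gene independent siRNA oligos per gene (default 3, each
#'   in its own well).
#' @param n_rows,n_cols plate format (default 16 x 24).
#' @param controls_per_plate named integer vector: wells per plate for roles
#'   `neg_ctrl`, `lethal_ctrl`, `lmna_ctrl`.
#' @param control_placement `"columns"` fills control wells from the last
#'   column top-to-bottom (the typical edge-column arrangement); `"random"`
#'   scatters them (seeded). The placements used are recorded in the layout.
#' @param gene_ids optional character vector of gene identifiers (default
#'   `g0001`...).
#' @param seed integer seed for the assignment permutation.
#' @return A [ScreenLayout-class] object.
#' @export
#' @examples
#' lay <- buildLibraryLayout(n_genes = 20, seed = 1)
#' nrow(libraryTable(lay))  # 60 library wells
buildLibraryLayout <- function(n_genes, oligos_per_gene = 3L,
                               n_rows = 16L, n_cols = 24L,
                               controls_per_plate = c(neg_ctrl = 8L,
                                                      lethal_ctrl = 4L,
                                                      lmna_ctrl = 4L),
                               control_placement = c("columns", "random"),
                               gene_ids = NULL, seed = 1L) {
  control_placement <- match.arg(control_placement)
  .checkTrue(n_genes >= 1, "n_genes must be >= 1")
  .checkTrue(oligos_per_gene >= 1, "oligos_per_gene must be >= 1")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  wells_per_plate <- n_rows * n_cols
  ctl <- controls_per_plate
  if (length(ctl) == 0) ctl <- c(neg_ctrl = 0L)
  .checkTrue(all(names(ctl) %in% c("neg_ctrl", "lethal_ctrl", "lmna_ctrl")),
             "controls_per_plate names must be neg_ctrl/lethal_ctrl/lmna_ctrl")
  n_ctl <- sum(ctl)
  if (n_ctl >= wells_per_plate) {
    stop("plate format too small for the requested controls", call. = FALSE)
  }
  capacity <- wells_per_plate - n_ctl
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
  }
  .checkTrue(length(gene_ids) == n_genes && !anyDuplicated(gene_ids),
             "gene_ids must be unique and of length n_genes")

  n_lib <- n_genes * oligos_per_gene
  n_plates <- ceiling(n_lib / capacity)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))

  ## every well of every plate, row-major within plate
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows),
                      plate = seq_len(n_plates))
  wells <- data.frame(
    plate_id = plate_ids[grid$plate],
    well = wellName(grid$row, grid$col),
    row = grid$row, col = grid$col,
    role = "empty", gene_id = NA_character_, oligo_id = NA_character_,
    stringsAsFactors = FALSE
  )

  ## control positions per plate
  ctl_roles <- rep(names(ctl), times = ctl)
  for (p in seq_len(n_plates)) {
    idx_plate <- which(wells$plate_id == plate_ids[p])
    if (n_ctl == 0) break
    if (control_placement == "columns") {
      ## fill from the last column, top to bottom, wrapping inward
      ord <- order(-wells$col[idx_plate], wells$row[idx_plate])
      pos <- idx_plate[ord][seq_len(n_ctl)]
    } else {
      pos <- withChildSeed(seed, "controls", plate_ids[p], expr = {
        sample(idx_plate, n_ctl)
      })
    }
    wells$role[pos] <- ctl_roles
  }

  ## library assignment: seeded permutation of (gene, oligo) pairs, spread
  ## evenly over the plates (balanced allocation keeps every plate dense
  ## enough for a stable median-polish fit), row-major within plate
  pairs <- expand.grid(oligo = seq_len(oligos_per_gene),
                       gene = seq_len(n_genes))
  perm <- withChildSeed(seed, "assignment", expr = sample(nrow(pairs)))
  pairs <- pairs[perm, ]
  per_plate <- rep(n_lib %/% n_plates, n_plates)
  extra <- n_lib %% n_plates
  if (extra > 0) per_plate[seq_len(extra)] <- per_plate[seq_len(extra)] + 1L
  lib_pos <- unlist(lapply(seq_len(n_plates), function(p) {
    free <- which(wells$role == "empty" & wells$plate_id == plate_ids[p])
    free[seq_len(per_plate[p])]
  }))
  wells$role[lib_pos] <- "library"
  wells$gene_id[lib_pos] <- gene_ids[pairs$gene]
  wells$oligo_id[lib_pos] <- sprintf("%s_o%d", gene_ids[pairs$gene],
                                     pairs$oligo)

  new("ScreenLayout", plate_ids = plate_ids, n_rows = n_rows,
      n_cols = n_cols, wells = wells, seed = as.integer(seed))
}
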