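# Field bookkeeping: arena assignment with anti-clustering, manifests,
# attack-record parsing, and print sheets for physical target production.

SLOT_COLOURS <- c("red", "green", "blue", "yellow")

#' Assign a population to trays, days, slots and positions
#'
#' Splits the population into `n_groups` groups of `group_size`, schedules
#' them across days and trays (default three trays over two days, so each
#' generation is fully exposed across two consecutive days), samples
#' in-tray positions uniformly with a minimum pairwise separation
#' (anti-clustering), and labels slots left to right with the fixed string
#' colour order red, green, blue, yellow.
#'
#' @param pop a `camo_population`.
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @param tray_mm tray side length in mm (default 530).
#' @param d_min minimum pairwise distance between prey in a tray (mm).
#' @param trays_per_day trays available per day (default 3).
#' @param max_retries rejection-sampling retries per tray before error.
#' @return an `arena_assignment` data.frame: `prey_id`, `generation`,
#'   `group`, `day`, `tray`, `slot`, `colour`, `x_mm`, `y_mm`.
#' @export
assign_arenas <- function(pop, cfg, seed = 1L, tray_mm = 530,
                          d_min = 100, trays_per_day = 3L,
                          max_retries = 1000L) {
  if (length(pop$genomes) %% cfg$group_size != 0) {
    stop("population size is not divisible by group size")
  }
  grouping <- default_grouping(pop, cfg)
  gseeds <- derive_seeds(seed, cfg$n_groups)
  rows <- lapply(seq_len(cfg$n_groups), function(g) {
    ids <- grouping$prey_id[grouping$group == g]
    pos <- sample_separated_positions(length(ids), tray_mm, d_min,
                                      gseeds[g], max_retries)
    ord <- order(pos[, 1]) # left to right defines the slot index
    slot <- integer(length(ids))
    slot[ord] <- seq_along(ids)
    data.frame(
      prey_id = ids, generation = pop$generation, group = g,
      day = ((g - 1L) %/% trays_per_day) + 1L,
      tray = ((g - 1L) %% trays_per_day) + 1L,
      slot = slot,
      colour = SLOT_COLOURS[((slot - 1L) %% length(SLOT_COLOURS)) + 1L],
      x_mm = pos[, 1], y_mm = pos[, 2], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("arena_assignment", "data.frame")
  out
}

# uniform positions in a square tray, all pairwise distances >= d_min
sample_separated_positions <- function(n, tray_mm, d_min, seed,
                                       max_retries) {
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      pos <- cbind(runif(n, 0, tray_mm), runif(n, 0, tray_mm))
      if (n == 1 || min(dist(pos)) >= d_min) {
        return(round(pos, 1))
      }
    }
    stop(sprintf(
      "could not place %d prey with separation %g mm in a %g mm tray",
      n, d_min, tray_mm))
  })
}

#' Export an arena assignment manifest CSV
#'
#' One row per prey with the exact header
#' `generation,day,tray,slot,colour,x_mm,y_mm,prey_id,image`; the file
#' re-imports losslessly with [utils::read.csv()].
#'
#' @param asg an `arena_assignment`.
#' @param path output CSV path.
#' @param image_dir directory prefix recorded in the `image` column.
#' @return `path`, invisibly.
#' @export
export_manifest <- function(asg, path, image_dir = "targets") {
  df <- data.frame(
    generation = asg$generation, day = asg$day, tray = asg$tray,
    slot = asg$slot, colour = asg$colour, x_mm = asg$x_mm,
    y_mm = asg$y_mm, prey_id = asg$prey_id,
    image = file.path(image_dir, paste0(asg$prey_id, ".png")),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse an attack-order CSV into validated attack records
#'
#' Accepts rows addressed either by prey id or by slot string colour
#' (resolved through the assignment's fixed left-to-right colour order).
#' Expected columns: `day` (optional when trays are unambiguous), `tray`,
#' `target` (colour name or prey id), `attack_index`, and optionally
#' `source` (`gate`, `video` or `manual`). Duplicate attack indices
#' within a tray, unknown trays/targets and duplicate attacks on one prey
#' are rejected with errors naming the offending row.
#'
#' @param path CSV path.
#' @param asg the generation's `arena_assignment`.
#' @return data.frame of attack records: `prey_id`, `group`,
#'   `attack_index`, `source`.
#' @export
parse_attack_csv <- function(path, asg) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tray", "target", "attack_index")
  if (!all(need %in% names(df))) {
    stop("attack CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!"day" %in% names(df)) {
    if (anyDuplicated(unique(asg[, c("day", "tray")])$tray)) {
      stop("attack CSV needs a 'day' column: tray ids repeat across days")
    }
    df$day <- asg$day[match(df$tray, asg$tray)]
  }
  if (!"source" %in% names(df)) df$source <- "manual"
  bad_src <- setdiff(unique(df$source), c("gate", "video", "manual"))
  if (length(bad_src)) stop("unknown attack source: ", bad_src[1])
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sel <- asg$day == row$day & asg$tray == row$tray
    if (!any(sel)) {
      stop(sprintf("row %d: unknown tray %s (day %s)", i, row$tray,
                   row$day))
    }
    tray_asg <- asg[sel, ]
    pid <- if (row$target %in% tray_asg$prey_id) {
      row$target
    } else if (tolower(row$target) %in% tray_asg$colour) {
      tray_asg$prey_id[tray_asg$colour == tolower(row$target)]
    } else {
      stop(sprintf("row %d: target '%s' is neither a prey id nor a slot colour in tray %s",
                   i, row$target, row$tray))
    }
    data.frame(prey_id = pid, group = tray_asg$group[1],
               attack_index = as.integer(row$attack_index),
               source = row$source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$attack_index < 1)) stop("attack_index must be >= 1")
  for (g in unique(out$group)) {
    ai <- out$attack_index[out$group == g]
    if (anyDuplicated(ai)) {
      stop(sprintf("duplicate attack_index %d in tray-day group %s (row %d)",
                   ai[duplicated(ai)][1], g,
                   which(out$group == g)[duplicated(ai)][1]))
    }
  }
  if (anyDuplicated(out$prey_id)) {
    stop("duplicate attack for prey ", out$prey_id[duplicated(out$prey_id)][1])
  }
  out
}

#' Render a labelled print sheet for a generation's targets
#'
#' Lays the rendered targets out on a white page in a fixed grid, resizing
#' each to the stated physical size at the stated resolution
#' (nearest-neighbour, as a printer driver would), with the prey index
#' printed beneath each cell. Deterministic: identical inputs give
#' bit-identical PNGs.
#'
#' @param targets list of `target_image`s.
#' @param path output PNG path.
#' @param ncol grid columns (default 4).
#' @param cell_mm physical target size `c(width, height)` in mm
#'   (default `c(18, 14)`, the printed shell dimensions).
#' @param dpi print resolution (default 180).
#' @param pad_px padding between cells.
#' @return invisible list with the page array and the cell pixel size.
#' @export
export_print_sheet <- function(targets, path, ncol = 4,
                               cell_mm = c(18, 14), dpi = 180,
                               pad_px = 6) {
  n <- length(targets)
  if (n == 0) stop("no targets to lay out")
  nrow_grid <- ceiling(n / ncol)
  cell_w <- round(cell_mm[1] * dpi / 25.4)
  cell_h <- round(cell_mm[2] * dpi / 25.4)
  cap_h <- 8L
  page_w <- ncol * (cell_w + pad_px) + pad_px
  page_h <- nrow_grid * (cell_h + cap_h + pad_px) + pad_px
  page <- array(1, c(page_h, page_w, 3))
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol
    cc <- (i - 1) %% ncol
    y0 <- pad_px + r * (cell_h + cap_h + pad_px)
    x0 <- pad_px + cc * (cell_w + pad_px)
    cell <- resize_nn(targets[[i]]$rgb, cell_h, cell_w)
    mask <- resize_nn_mask(targets[[i]]$alpha_mask, cell_h, cell_w)
    for (ch in 1:3) {
      sub <- page[y0 + seq_len(cell_h), x0 + seq_len(cell_w), ch]
      lay <- cell[, , ch]
      sub[mask] <- lay[mask]
      page[y0 + seq_len(cell_h), x0 + seq_len(cell_w), ch] <- sub
    }
    page <- draw_digits(page, sprintf("%02d", i), y0 + cell_h + 2L,
                        x0 + 1L)
  }
  png::writePNG(page, path)
  invisible(list(page = page, cell_px = c(cell_w, cell_h)))
}

resize_nn <- function(img, h, w) {
  yi <- pmax(1L, ceiling(seq_len(h) / h * dim(img)[1]))
  xi <- pmax(1L, ceiling(seq_len(w) / w * dim(img)[2]))
  img[yi, xi, , drop = FALSE]
}

resize_nn_mask <- function(mask, h, w) {
  yi <- pmax(1L, ceiling(seq_len(h) / h * nrow(mask)))
  xi <- pmax(1L, ceiling(seq_len(w) / w * ncol(mask)))
  mask[yi, xi, drop = FALSE]
}

# 3x5 bitmap digits for captions
.DIGIT_FONT <- list(
  "0" = c(7, 5, 5, 5, 7), "1" = c(2, 6, 2, 2, 7), "2" = c(7, 1, 7, 4, 7),
  "3" = c(7, 1, 7, 1, 7), "4" = c(5, 5, 7, 1, 1), "5" = c(7, 4, 7, 1, 7),
  "6" = c(7, 4, 7, 5, 7), "7" = c(7, 1, 2, 2, 2), "8" = c(7, 5, 7, 5, 7),
  "9" = c(7, 5, 7, 1, 7)
)

draw_digits <- function(page, text, y0, x0) {
  x <- x0
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- .DIGIT_FONT[[ch]]
    if (!is.null(glyph)) {
      for (r in 1:5) {
        bits <- bitwAnd(glyph[r], c(4L, 2L, 1L)) > 0
        for (c in 1:3) {
          if (bits[c]) page[y0 + r, x + c, ] <- 0
        }
      }
    }
    x <- x + 4L
  }
  page
}
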