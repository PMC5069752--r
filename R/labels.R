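#' Describe a printable label sheet
#'
#' Geometry of a sticker sheet: a grid of `columns` x `rows` labels on a
#' page, with outer margins, each label carrying an (optional) Code 128
#' barcode and the identifier text beneath it.  The default — US letter,
#' half-inch margins, 4 x 10 labels — fits a barcode plus a 4-12
#' character CualID comfortably; commercial cryogenic sticker sheets vary
#' by vendor, so every dimension can be overridden to match the sheet in
#' the printer tray.
#'
#' @param columns,rows labels per row / rows per page.
#' @param page_width,page_height page size in inches (default US letter).
#' @param margin outer page margin in inches.
#' @param label_width,label_height label size in inches; by default the
#'   printable area is divided evenly by the grid.
#' @param include_barcode draw a Code 128 barcode above the text?
#' @param text_field which identifier(s) to print: `"cualid"`, `"uuid"`
#'   or `"both"`.
#' @return a `label_sheet_spec` list.
#' @export
label_sheet_spec <- function(columns = 4L, rows = 10L,
                             page_width = 8.5, page_height = 11,
                             margin = 0.5,
                             label_width = NULL, label_height = NULL,
                             include_barcode = TRUE,
                             text_field = c("cualid", "uuid", "both")) {
  text_field <- match.arg(text_field)
  columns <- as.integer(columns)
  rows <- as.integer(rows)
  if (columns < 1L || rows < 1L) {
    cualid_error("the sheet needs at least one label cell",
                 "cualid_arg_error")
  }
  avail_w <- page_width - 2 * margin
  avail_h <- page_height - 2 * margin
  if (is.null(label_width)) label_width <- avail_w / columns
  if (is.null(label_height)) label_height <- avail_h / rows
  if (columns * label_width > avail_w + 1e-9 ||
      rows * label_height > avail_h + 1e-9) {
    cualid_error("labels do not fit on the page within the margins",
                 "cualid_layout_error")
  }
  structure(list(columns = columns, rows = rows,
                 page_width = page_width, page_height = page_height,
                 margin = margin, label_width = label_width,
                 label_height = label_height,
                 include_barcode = include_barcode,
                 text_field = text_field),
            class = "label_sheet_spec")
}

label_text_for <- function(ids, field) {
  switch(field,
         cualid = ids$cualid,
         uuid = ids$uuid,
         both = paste(ids$cualid, ids$uuid, sep = "\n"))
}

# Deterministic placement of each label: page number and the (x, y) of
# the label's lower-left corner in inches from the page's lower-left.
sheet_layout <- function(n_labels, spec) {
  per_page <- spec$columns * spec$rows
  idx <- seq_len(n_labels) - 1L
  page <- idx %/% per_page + 1L
  cell <- idx %% per_page
  col <- cell %% spec$columns
  row <- cell %/% spec$columns  # row 0 = top row
  data.frame(
    page = page,
    x = spec$margin + col * spec$label_width,
    y = spec$page_height - spec$margin - (row + 1L) * spec$label_height)
}

draw_barcode <- function(widths, vp) {
  # quiet zone of 10 modules on each side
  total <- sum(widths) + 20L
  edges <- cumsum(c(10L, widths)) / total
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  bar <- seq_along(widths) %% 2L == 1L  # widths alternate bar, space, ...
  grid::grid.rect(
    x = grid::unit(starts[bar], "npc"), y = grid::unit(0, "npc"),
    width = grid::unit((ends - starts)[bar], "npc"),
    height = grid::unit(1, "npc"),
    just = c("left", "bottom"),
    gp = grid::gpar(fill = "black", col = NA), vp = vp)
}

#' Render minted identifiers to a PDF label sheet
#'
#' One label per identifier, in minting order, filling each page row by
#' row and overflowing onto further pages; each label shows the Code 128
#' barcode of its CualID (scannable with any standard reader) with the
#' identifier text beneath it.  Layout is a pure function of the inputs,
#' so identical inputs give identical page placement.
#'
#' @param ids a `cualid_set` (or data frame with `uuid` and `cualid`).
#' @param path output PDF path.
#' @param spec a [label_sheet_spec()].
#' @return invisibly, a list with `path`, `pages` and `labels` (the
#'   per-label layout table).
#' @export
render_sheet <- function(ids, path, spec = label_sheet_spec()) {
  if (is.character(ids)) {
    ids <- data.frame(uuid = NA_character_, cualid = tolower(ids),
                      stringsAsFactors = FALSE)
  }
  if (nrow(ids) == 0L) {
    cualid_error("`ids` must contain at least one identifier",
                 "cualid_arg_error")
  }
  layout <- sheet_layout(nrow(ids), spec)
  texts <- label_text_for(ids, spec$text_field)
  pages <- max(layout$page)
  grDevices::pdf(path, width = spec$page_width, height = spec$page_height,
                 onefile = TRUE, useDingbats = FALSE)
  on.exit(grDevices::dev.off())
  for (p in seq_len(pages)) {
    grid::grid.newpage()
    on_page <- which(layout$page == p)
    for (i in on_page) {
      vp_label <- grid::viewport(
        x = grid::unit(layout$x[i], "in"), y = grid::unit(layout$y[i], "in"),
        width = grid::unit(spec$label_width, "in"),
        height = grid::unit(spec$label_height, "in"),
        just = c("left", "bottom"))
      grid::pushViewport(vp_label)
      text_cex <- if (spec$text_field == "cualid") 0.8 else 0.45
      if (spec$include_barcode) {
        code <- encode_code128(ids$cualid[i])
        vp_bar <- grid::viewport(
          x = 0.5, y = grid::unit(0.95, "npc"),
          width = grid::unit(0.9, "npc"), height = grid::unit(0.5, "npc"),
          just = c("centre", "top"))
        draw_barcode(code$widths, vp_bar)
        grid::grid.text(texts[i], x = 0.5, y = grid::unit(0.38, "npc"),
                        just = c("centre", "top"),
                        gp = grid::gpar(fontfamily = "mono",
                                        cex = text_cex))
      } else {
        grid::grid.text(texts[i], x = 0.5, y = 0.5,
                        gp = grid::gpar(fontfamily = "mono",
                                        cex = text_cex))
      }
      grid::popViewport()
    }
  }
  invisible(list(path = path, pages = pages, labels = layout))
}
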