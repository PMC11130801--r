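# Minimal XLSX (first worksheet) reader.
#
# An .xlsx file is a zip archive of XML parts; this reads just what a
# rectangular data table needs: the first sheet in workbook order, shared
# and inline strings, and numeric cells. Formulas contribute their cached
# value. Anything fancier (styles, dates-as-numbers, multiple sheets) is
# out of scope for cohort tables.

col_letter_to_index <- function(ref) {
  letters_part <- gsub("[0-9]", "", ref)
  chars <- utf8ToInt(letters_part) - utf8ToInt("A") + 1L
  Reduce(function(acc, d) acc * 26L + d, chars, accumulate = FALSE)
}

read_xlsx_cells <- function(path) {
  tmp <- tempfile("xlsx_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- tryCatch(utils::unzip(path, exdir = tmp),
                    warning = function(w)
                      cohorteq_error("cohorteq_unreadable_file",
                                     paste0("cannot unzip xlsx: ", path)),
                    error = function(e)
                      cohorteq_error("cohorteq_unreadable_file",
                                     paste0("cannot unzip xlsx: ", path)))
  wb_path <- file.path(tmp, "xl", "workbook.xml")
  rels_path <- file.path(tmp, "xl", "_rels", "workbook.xml.rels")
  if (!file.exists(wb_path))
    cohorteq_error("cohorteq_unreadable_file",
                   paste0("not an xlsx workbook: ", path))

  wb <- xml2::xml_ns_strip(xml2::read_xml(wb_path))
  first_sheet <- xml2::xml_find_first(wb, ".//sheet")
  if (is.na(xml2::xml_name(first_sheet)))
    cohorteq_error("cohorteq_empty_table", paste0("workbook has no sheets: ", path))
  rid <- xml2::xml_attr(first_sheet, "id")  # ns-stripped r:id

  rels <- xml2::xml_ns_strip(xml2::read_xml(rels_path))
  rel <- xml2::xml_find_first(rels, sprintf(".//Relationship[@Id='%s']", rid))
  target <- xml2::xml_attr(rel, "Target")
  sheet_path <- file.path(tmp, "xl", sub("^/?(xl/)?", "", target))

  shared <- character()
  ss_path <- file.path(tmp, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::xml_ns_strip(xml2::read_xml(ss_path))
    shared <- vapply(xml2::xml_find_all(ss, ".//si"), function(si) {
      paste0(xml2::xml_text(xml2::xml_find_all(si, ".//t")), collapse = "")
    }, character(1))
  }

  sheet <- xml2::xml_ns_strip(xml2::read_xml(sheet_path))
  rows <- xml2::xml_find_all(sheet, ".//sheetData/row")
  if (length(rows) == 0L)
    cohorteq_error("cohorteq_empty_table", paste0("worksheet is empty: ", path))

  cells <- list()
  max_col <- 0L
  for (i in seq_along(rows)) {
    row_num <- as.integer(xml2::xml_attr(rows[[i]], "r")) %||% i
    if (is.na(row_num)) row_num <- i
    for (c_node in xml2::xml_find_all(rows[[i]], "./c")) {
      ref <- xml2::xml_attr(c_node, "r")
      col <- if (is.na(ref)) NA_integer_ else col_letter_to_index(ref)
      type <- xml2::xml_attr(c_node, "t")
      value <- if (!is.na(type) && type == "inlineStr") {
        paste0(xml2::xml_text(xml2::xml_find_all(c_node, ".//is//t")), collapse = "")
      } else {
        v <- xml2::xml_find_first(c_node, "./v")
        if (is.na(xml2::xml_name(v))) NA_character_
        else if (!is.na(type) && type == "s") shared[as.integer(xml2::xml_text(v)) + 1L]
        else xml2::xml_text(v)
      }
      cells[[length(cells) + 1L]] <- list(row = row_num, col = col, value = value)
      if (!is.na(col)) max_col <- max(max_col, col)
    }
  }
  if (max_col == 0L)
    cohorteq_error("cohorteq_empty_table", paste0("worksheet has no cells: ", path))

  row_ids <- sort(unique(vapply(cells, `[[`, 1L, "row")))
  mat <- matrix(NA_character_, nrow = length(row_ids), ncol = max_col)
  row_pos <- stats::setNames(seq_along(row_ids), row_ids)
  for (cell in cells) {
    if (is.na(cell$col)) next
    mat[row_pos[[as.character(cell$row)]], cell$col] <- cell$value
  }

  header <- mat[1L, ]
  if (anyNA(header))
    cohorteq_error("cohorteq_ragged_rows",
                   paste0("header row has empty cells: ", path))
  body <- mat[-1L, , drop = FALSE]
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  df
}
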