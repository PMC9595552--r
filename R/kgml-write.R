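#' Write a pathway graph as KGML
#'
#' Serialises a [pathway_graph()] back to KGML XML.  Expanded children are
#' emitted as ordinary `<entry>` elements with synthetic ids
#' (`"<parentid>_<n>"`) plus a `funhop_parent` attribute linking to their
#' parent, so the output stays loadable by generic KGML consumers while
#' [read_kgml()] restores the parent/child structure.  Differential-expression
#' colors attached by [annotate_graph()] are written into the graphics
#' `bgcolor`.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(graph, path) {
  validate_pathway_graph(graph)
  attrs <- graph$attrs
  if (!length(attrs)) {
    attrs <- c(name = graph$pathway_id, title = graph$title)
  }
  doc <- xml2::xml_new_root("pathway")
  for (nm in names(attrs)) xml2::xml_set_attr(doc, nm, attrs[[nm]])

  for (e in structural_entries(graph)) {
    add_entry_node(doc, e)
    for (cid in e$children) {
      add_entry_node(doc, graph$entries[[cid]], funhop_parent = e$id)
    }
  }
  for (r in graph$reactions) {
    rn <- xml2::xml_add_child(doc, "reaction", id = r$entry_id,
                              name = r$reaction_id,
                              type = if (r$reversible) "reversible"
                                     else "irreversible")
    for (nm in names(r$attrs)) xml2::xml_set_attr(rn, nm, r$attrs[[nm]])
    for (s in r$substrates) xml2::xml_add_child(rn, "substrate", id = s,
                                                name = s)
    for (p in r$products) xml2::xml_add_child(rn, "product", id = p,
                                              name = p)
  }
  for (rel in graph$relations) {
    ln <- xml2::xml_add_child(doc, "relation", entry1 = rel$entry1,
                              entry2 = rel$entry2, type = rel$relation_type)
    for (nm in names(rel$attrs)) xml2::xml_set_attr(ln, nm, rel$attrs[[nm]])
    for (st in rel$subtypes) {
      xml2::xml_add_child(ln, "subtype", name = st$name, value = st$value)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_entry_node <- function(doc, e, funhop_parent = NULL) {
  en <- xml2::xml_add_child(doc, "entry", id = e$id, name = e$name,
                            type = e$type)
  if (!is.null(e$link)) xml2::xml_set_attr(en, "link", e$link)
  if (!is.null(e$reaction)) xml2::xml_set_attr(en, "reaction", e$reaction)
  for (nm in names(e$extra)) xml2::xml_set_attr(en, nm, e$extra[[nm]])
  if (!is.null(funhop_parent)) {
    xml2::xml_set_attr(en, "funhop_parent", funhop_parent)
  }
  gfx_list <- e$graphics
  if (!length(gfx_list) && !is.null(e$annotation)) gfx_list <- list(character())
  for (gfx in gfx_list) {
    gn <- xml2::xml_add_child(en, "graphics")
    if (!is.null(e$annotation$color)) gfx["bgcolor"] <- e$annotation$color
    if (!is.null(e$annotation$symbol) &&
        (is.na(gfx["name"]) || !nzchar(gfx["name"]))) {
      gfx["name"] <- e$annotation$symbol
    }
    gfx <- gfx[!is.na(gfx)]
    for (nm in names(gfx)) xml2::xml_set_attr(gn, nm, gfx[[nm]])
  }
  for (cid in e$components) xml2::xml_add_child(en, "component", id = cid)
  en
}
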