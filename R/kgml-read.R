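#' Read a KGML pathway file
#'
#' Parses a KEGG KGML (v0.7.x) XML document into a [pathway_graph()].  Gene
#' identifiers are obtained by splitting the entry `name` attribute on
#' whitespace.  Unknown attributes are retained verbatim so that
#' [write_kgml()] can reproduce them.  Entries written by [write_kgml()] for
#' expanded children (carrying a `funhop_parent` attribute) are re-attached
#' to their parent entry, making read/write a lossless round trip.
#'
#' @param path Path to a KGML XML file.
#' @return A [pathway_graph()].
#' @export
#' @examples
#' kgml <- system.file("extdata", "toy_pathway.xml", package = "funhop")
#' read_kgml(kgml)
read_kgml <- function(path) {
  doc <- xml2::read_xml(path)   # malformed XML -> xml2 error naming the line
  if (xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document: root element is <", xml2::xml_name(doc), ">")
  }
  attrs <- xml2::xml_attrs(doc)

  entries <- list()
  for (node in xml2::xml_find_all(doc, "./entry")) {
    e <- parse_entry(node)
    entries[[e$id]] <- e
  }

  # re-attach expanded children written by write_kgml()
  for (e in entries) {
    pid <- unname(e$extra["funhop_parent"])
    if (!is.na(pid) && !is.null(entries[[pid]])) {
      entries[[e$id]]$parent <- pid
      entries[[e$id]]$extra <-
        e$extra[setdiff(names(e$extra), "funhop_parent")]
      entries[[pid]]$children <- c(entries[[pid]]$children, e$id)
    }
  }

  reactions <- lapply(xml2::xml_find_all(doc, "./reaction"), parse_reaction)
  relations <- lapply(xml2::xml_find_all(doc, "./relation"), parse_relation)

  pathway_graph(
    pathway_id = unname(attrs["name"] %||% ""),
    title = unname(attrs["title"] %||% ""),
    entries = entries,
    reactions = reactions,
    relations = relations,
    attrs = attrs
  )
}

KGML_ENTRY_CORE_ATTRS <- c("id", "name", "type", "link", "reaction")

parse_entry <- function(node) {
  a <- xml2::xml_attrs(node)
  type <- unname(a["type"])
  if (is.na(type)) type <- "other"
  if (!type %in% KGML_ENTRY_TYPES) {
    warning("unknown entry type '", type, "' for entry id ", a["id"],
            "; kept verbatim", call. = FALSE)
  }
  name <- unname(a["name"])
  if (is.na(name)) name <- ""
  gene_ids <- if (type %in% c("gene", "ortholog") && nzchar(name)) {
    strsplit(trimws(name), "\\s+")[[1]]
  } else {
    character()
  }
  graphics <- lapply(xml2::xml_find_all(node, "./graphics"), xml2::xml_attrs)
  components <- vapply(xml2::xml_find_all(node, "./component"),
                       function(cn) xml2::xml_attr(cn, "id"), character(1))
  extra <- a[setdiff(names(a), KGML_ENTRY_CORE_ATTRS)]
  new_entry(
    id = unname(a["id"]), type = type, name = name, gene_ids = gene_ids,
    graphics = graphics,
    link = if (!is.na(a["link"])) unname(a["link"]) else NULL,
    reaction = if (!is.na(a["reaction"])) unname(a["reaction"]) else NULL,
    components = components, extra = extra
  )
}

parse_reaction <- function(node) {
  a <- xml2::xml_attrs(node)
  subs <- vapply(xml2::xml_find_all(node, "./substrate"),
                 function(n) xml2::xml_attr(n, "id"), character(1))
  prods <- vapply(xml2::xml_find_all(node, "./product"),
                  function(n) xml2::xml_attr(n, "id"), character(1))
  new_reaction(
    reaction_id = unname(a["name"] %||% ""),
    entry_id = unname(a["id"]),
    substrates = subs, products = prods,
    reversible = identical(unname(a["type"]), "reversible"),
    attrs = a[setdiff(names(a), c("id", "name", "type"))]
  )
}

parse_relation <- function(node) {
  a <- xml2::xml_attrs(node)
  subtypes <- lapply(xml2::xml_find_all(node, "./subtype"), function(sn) {
    list(name = xml2::xml_attr(sn, "name"),
         value = xml2::xml_attr(sn, "value"))
  })
  new_relation(
    entry1 = unname(a["entry1"]), entry2 = unname(a["entry2"]),
    relation_type = unname(a["type"] %||% ""),
    subtypes = subtypes,
    attrs = a[setdiff(names(a), c("entry1", "entry2", "type"))]
  )
}
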