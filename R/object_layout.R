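#' Field specification for the record-layout calculator
#'
#' @param name field name.
#' @param size_bytes field size in bytes (>= 1).
#' @param alignment_bytes required alignment, a power of two.  Defaults to
#'   the size (natural alignment of scalar fields on 64-bit platforms).
#' @return object of class `field_spec`.
#' @export
field_spec <- function(name, size_bytes, alignment_bytes = size_bytes) {
  if (!is.finite(size_bytes) || size_bytes < 1)
    stop("size_bytes must be >= 1")
  if (!is.finite(alignment_bytes) || alignment_bytes < 1 ||
      bitwAnd(as.integer(alignment_bytes), as.integer(alignment_bytes) - 1L) != 0L)
    stop("alignment_bytes must be a power of two")
  structure(list(name = as.character(name),
                 size_bytes = as.integer(size_bytes),
                 alignment_bytes = as.integer(alignment_bytes)),
            class = "field_spec")
}

#' Aligned layout of an ordered record
#'
#' Assigns offsets sequentially in declaration order, rounding each
#' offset up to the field's alignment, and rounds the total size up to
#' the maximum field alignment (the rule C++ compilers apply to plain
#' structs on 64-bit architectures, where 8-byte scalars align to 64-bit
#' word boundaries).  Fields are never reordered.
#'
#' @param fields list of [field_spec()] objects (non-empty).
#' @return object of class `struct_layout`: data frame `fields` with
#'   columns `name`, `size`, `alignment`, `offset`; scalars
#'   `total_bytes`, `padding_bytes`, `data_bytes`.
#' @examples
#' struct_layout(list(field_spec("target_index", 2),
#'                    field_spec("delay_syn_id", 4),
#'                    field_spec("weight", 8)))
#' @export
struct_layout <- function(fields) {
  if (!is.list(fields) || length(fields) == 0)
    stop("fields must be a non-empty list of field_spec objects")
  if (!all(vapply(fields, inherits, logical(1), "field_spec")))
    stop("all fields must be field_spec objects")
  off <- 0L
  offsets <- integer(length(fields))
  for (i in seq_along(fields)) {
    a <- fields[[i]]$alignment_bytes
    off <- as.integer(ceiling(off / a) * a)
    offsets[i] <- off
    off <- off + fields[[i]]$size_bytes
  }
  max_align <- max(vapply(fields, `[[`, integer(1), "alignment_bytes"))
  total <- as.integer(ceiling(off / max_align) * max_align)
  data_bytes <- sum(vapply(fields, `[[`, integer(1), "size_bytes"))
  structure(list(
    fields = data.frame(
      name = vapply(fields, `[[`, character(1), "name"),
      size = vapply(fields, `[[`, integer(1), "size_bytes"),
      alignment = vapply(fields, `[[`, integer(1), "alignment_bytes"),
      offset = offsets),
    total_bytes = total,
    padding_bytes = total - data_bytes,
    data_bytes = data_bytes), class = "struct_layout")
}

#' Field catalog of the simulator's synapse records
#'
#' The 3g static synapse stores a 4 B type id, an 8 B target pointer, an
#' 8 B integer delay and an 8 B double weight (32 B aligned).  The 4g
#' condensed record replaces the pointer by a 2 B thread-local target
#' index and packs delay and type into one 4 B word:
#' \{target index, delay + synapse type, weight\} -- 16 B aligned, with
#' 2 B of padding after the index.  STDP variants append the 8 B double
#' synaptic trace.  The 3g field order is a convention; its 32 B total is
#' order-invariant for these fields.
#'
#' @param generation `"3g"` or `"4g"`.
#' @param model `"static"` or `"stdp"`.
#' @return list of [field_spec()]s, suitable for [struct_layout()].
#' @export
synapse_catalog <- function(generation = c("4g", "3g"),
                            model = c("static", "stdp")) {
  generation <- match.arg(generation)
  model <- match.arg(model)
  fields <- if (generation == "3g") {
    list(field_spec("syn_type", 4),
         field_spec("target_ptr", 8),
         field_spec("delay", 8),
         field_spec("weight", 8))
  } else {
    list(field_spec("target_index", 2),
         field_spec("delay_syn_id", 4),
         field_spec("weight", 8))
  }
  if (model == "stdp")
    fields <- c(fields, list(field_spec("trace", 8)))
  fields
}

#' Pack delay and synapse type into one 4-byte word
#'
#' The delay, an integer multiple of the simulation step `h`, occupies a
#' 24-bit field and the synapse-type id an 8-bit field of a common 4 B
#' word.  At `h = 0.1` ms the representable delay range is
#' `2^24 * h ~ 1678` s and the number of synapse types is capped at
#' `2^8 = 256`.
#'
#' @param delay_steps integer in `[0, 2^24)`.
#' @param syn_id integer in `[0, 256)`.
#' @return the packed word as a numeric scalar in `[0, 2^32)`.
#' @export
pack_delay_type <- function(delay_steps, syn_id) {
  if (any(delay_steps < 0) || any(delay_steps >= 2^24) ||
      any(delay_steps != floor(delay_steps)))
    stop("delay_steps must be an integer in [0, 2^24)")
  if (any(syn_id < 0) || any(syn_id >= 256) || any(syn_id != floor(syn_id)))
    stop("syn_id must be an integer in [0, 256)")
  delay_steps * 256 + syn_id
}

#' @rdname pack_delay_type
#' @param word a packed word produced by [pack_delay_type()].
#' @return `unpack_delay_type`: list with `delay_steps` and `syn_id`.
#' @export
unpack_delay_type <- function(word) {
  if (any(word < 0) || any(word >= 2^32) || any(word != floor(word)))
    stop("word must be an integer in [0, 2^32)")
  list(delay_steps = word %/% 256, syn_id = word %% 256)
}

#' Does a thread-local node count fit the 2-byte index scheme?
#'
#' Indexed target addressing stores the target as its position in the
#' vector of VP-local nodes using a 2 B unsigned index, which caps the
#' number of local nodes at `2^16 - 1 = 65535`.
#'
#' @param n_local thread-local node count.
#' @return logical.
#' @export
fits_short_index <- function(n_local) {
  n_local <= 65535
}
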