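# Default semantic-network schema: 9 node types, 12 edge types (A1-A12).
# Edge types marked `similarity: true` are the structure/sequence
# neighboring links; together with A6 they are stored symmetric with a
# zero diagonal (self-similarity is never recorded -- see package docs).
name: semantic_network_default
node_types:
  - compound
  - protein
  - chebi_type
  - substructure
  - side_effect
  - disease
  - go_annotation
  - pathway
  - tissue
edge_types:
  - id: A1
    predicate: "has ChEBI type"
    reverse_predicate: "type of"
    from: compound
    to: chebi_type
  - id: A2
    predicate: "binds to"
    reverse_predicate: "binds to"
    from: compound
    to: protein
  - id: A3
    predicate: "has part"
    reverse_predicate: "part of"
    from: compound
    to: substructure
  - id: A4
    predicate: "induced by"
    reverse_predicate: "induces"
    from: side_effect
    to: compound
  - id: A5
    predicate: "treated by"
    reverse_predicate: "treats"
    from: disease
    to: compound
  - id: A6
    predicate: "interacts with"
    reverse_predicate: "interacts with"
    from: protein
    to: protein
  - id: A7
    predicate: "has GO annotation"
    reverse_predicate: "annotation of"
    from: protein
    to: go_annotation
  - id: A8
    predicate: "caused by"
    reverse_predicate: "causes"
    from: disease
    to: protein
  - id: A9
    predicate: "has participants"
    reverse_predicate: "participates in"
    from: pathway
    to: protein
  - id: A10
    predicate: "expresses"
    reverse_predicate: "expressed in"
    from: tissue
    to: protein
  - id: A11
    predicate: "similar to"
    reverse_predicate: "similar to"
    from: compound
    to: compound
    similarity: true
  - id: A12
    predicate: "similar to"
    reverse_predicate: "similar to"
    from: protein
    to: protein
    similarity: true
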