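# Surface grammar

The concrete syntax accepted by `nrc_parse()`. Whitespace is insignificant;
`#` starts a comment to end of line. This syntax is this package's own
concrete notation for the comprehension language; no compatibility with any
other system's surface syntax is claimed.

```ebnf
program      = assignment { assignment } ;
assignment   = IDENT ":=" bag_expr ;

bag_expr     = bag_term { "++" bag_term } ;            (* bag union *)
bag_term     = comprehension
             | conditional
             | "dedup" "(" bag_expr ")"
             | "groupBy" "[" names "->" IDENT "]" "(" bag_expr ")"
             | "sumBy" "[" names ";" names "]" "(" bag_expr ")"
             | tuple                                    (* singleton bag *)
             | path ;                                   (* bag-typed path *)

comprehension = "for" IDENT "in" path "union" bag_term ;
conditional   = "if" "(" predicate ")" "then" bag_term ;

tuple        = "{" [ IDENT ":=" field_value
                     { "," IDENT ":=" field_value } ] "}" ;
field_value  = bag_term | scalar_expr ;

predicate    = conj { "||" conj } ;
conj         = atom { "&&" atom } ;
atom         = "(" predicate ")"
             | scalar_expr [ cmp_op scalar_expr ] ;
cmp_op       = "==" | "!=" | "<" | "<=" | ">" | ">=" ;

scalar_expr  = term { ("+" | "-") term } ;
term         = factor { ("*" | "/") factor } ;
factor       = NUMBER | STRING | "true" | "false"
             | path | "(" scalar_expr ")"
             | "mklabel" "(" STRING { "," IDENT ":=" scalar_expr } ")" ;

path         = IDENT { "." IDENT } ;
names        = IDENT { "," IDENT } ;
```

Notes

* A bare identifier resolves to the enclosing comprehension variable of
  that name if one is in scope, otherwise to an input collection.
* A tuple in bag position (comprehension body, conditional branch,
  assignment) denotes the singleton bag containing it.
* Comprehension bodies and conditional branches bind tighter than `++`, so
  `for x in X union { t } ++ e` unions the whole comprehension with `e`.
* `NUMBER` without a decimal point is an int; with one it is a real.
* Conditionals appear in bag positions only; there is no scalar-position
  `if`.
* `mklabel(...)` and `labels(...)` occur in printed shredded component
  programs (label construction and label domains); user programs do not
  need them.
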