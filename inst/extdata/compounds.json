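{
  "SN38": {"formula": "C22H20N2O5",
           "note": "7-ethyl-10-hydroxycamptothecin"},
  "2": {"formula": "C24H25N3O5", "amine": "CH5N",
        "note": "7-ethyl-9-(N-methylamino)methyl-10-hydroxycamptothecin"},
  "3": {"formula": "C27H29N3O6", "amine": "C4H9NO",
        "note": "7-ethyl-9-(N-morpholino)methyl-10-hydroxycamptothecin"},
  "4": {"formula": "C23H22N2O6",
        "note": "7-ethyl-9-hydroxymethyl-10-hydroxycamptothecin"}
}
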