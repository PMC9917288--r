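{
  "name": "synthetic reference serpin (AtSerpin1-like stand-in)",
  "protein": "MDKEAVSQNTLSREIAKDSGETNKQVRDLTYYAPCLKQKTHQQAGYRAKVCFKAWHRMKCMNNDAGKALWLRSDGHNKHPLQFEDEIWAGKVGKDIKFTGYILFCNRYLLCDRRCSMTSEVHHCDHDTGYPTEIGLKILRYRWDPSMSITNNHMGPTSFTLPFMKESFNDLKRWFAGQAEHRFWNTMGIAGRFEGPFNEGDAHPLYTDVLYRVHYNHFPVPMDFKHERFKKWFLKVCQWMVVDLQLVYCRIRHIRIYVQFWCLWEMAGRGGFDRGPCKVWWFSRYMMPWGIMSHCLSEMKDAFLLVYMKHLEKPAEWPWAQRPYHYHPSVANFMAVRMKECDSSMLRHFYAYEEGTEAAAATAVKITLRSAKTPLDMHGLFVPQMWCALRVMFCI",
  "rcl_start": 352,
  "rcl_end": 369,
  "core_blocks": [
    [30, 70],
    [85, 125],
    [140, 180],
    [195, 235],
    [250, 290],
    [305, 345]
  ]
}
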