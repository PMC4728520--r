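Name: Pseudane-III
Formula: C12H14ON
PrecursorMZ: 188.106990
Comment: provenance=literature
Num Peaks: 5
132 100
146 100
159 100
170 100
188 100

Name: Pseudane-IV
Formula: C13H16ON
PrecursorMZ: 202.122641
Comment: provenance=commercial_standard
Num Peaks: 6
132 100
146 100
159 100
172 100
183 100
202 100

Name: Pseudane-V
Formula: C14H18ON
PrecursorMZ: 216.138291
Comment: provenance=literature
Num Peaks: 7
132 100
146 100
159 100
172 100
186 100
197 100
216 100

Name: Pseudane-VI
Formula: C15H20ON
PrecursorMZ: 230.153941
Comment: provenance=commercial_standard
Num Peaks: 7
132 100
146 100
159 100
172 100
186 100
200 100
230 100

Name: Pseudane-VII
Formula: C16H22ON
PrecursorMZ: 244.169591
Comment: provenance=literature
Num Peaks: 7
132 100
146 100
159 100
172 100
186 100
200 100
244 100

Name: Pseudane-VIII
Formula: C17H24ON
PrecursorMZ: 258.185241
Comment: provenance=commercial_standard
Num Peaks: 7
132 100
146 100
159 100
172 100
186 100
200 100
258 100

Name: Pseudane-IX
Formula: C18H26ON
PrecursorMZ: 272.200891
Comment: provenance=literature
Num Peaks: 7
132 100
146 100
159 100
172 100
186 100
200 100
272 100

Name: Pseudane-X
Formula: C19H28ON
PrecursorMZ: 286.216541
Comment: provenance=literature
Num Peaks: 7
146 100
159 100
172 100
186 100
200 100
214 100
286 100

Name: Pseudane-XI
Formula: C20H30ON
PrecursorMZ: 300.232191
Comment: provenance=literature
Num Peaks: 7
146 100
159 100
172 100
186 100
200 100
214 100
300 100
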