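BEGIN IONS
TITLE=M2_01
PEPMASS=188.1070
RTINSECONDS=273.6
132 100
146 100
159 100
170 100
188 100
END IONS

BEGIN IONS
TITLE=M2_02
PEPMASS=202.1227
RTINSECONDS=319.2
132 100
146 100
159 100
172 100
183 100
202 100
END IONS

BEGIN IONS
TITLE=M2_03
PEPMASS=216.1382
RTINSECONDS=359.4
132 100
146 100
159 100
172 100
186 100
200 100
216 100
END IONS

BEGIN IONS
TITLE=M2_04
PEPMASS=216.1382
RTINSECONDS=365.4
132 100
146 100
159 100
172 100
186 100
197 100
216 100
END IONS

BEGIN IONS
TITLE=M2_05
PEPMASS=230.1539
RTINSECONDS=402.6
132 100
146 100
159 100
172 100
186 100
200 100
230 100
END IONS

BEGIN IONS
TITLE=M2_06
PEPMASS=230.1539
RTINSECONDS=409.8
132 100
146 100
159 100
172 100
186 100
200 100
230 100
END IONS

BEGIN IONS
TITLE=M2_07
PEPMASS=244.1695
RTINSECONDS=453.0
132 100
146 100
159 100
172 100
186 100
200 100
244 100
END IONS

BEGIN IONS
TITLE=M2_08
PEPMASS=258.1851
RTINSECONDS=497.4
132 100
146 100
159 100
172 100
186 100
200 100
258 100
END IONS

BEGIN IONS
TITLE=M2_09
PEPMASS=272.2007
RTINSECONDS=540.0
132 100
146 100
159 100
172 100
186 100
200 100
272 100
END IONS

BEGIN IONS
TITLE=M2_10
PEPMASS=286.2164
RTINSECONDS=580.2
146 100
159 100
172 100
186 100
200 100
214 100
286 100
END IONS

BEGIN IONS
TITLE=M2_11
PEPMASS=300.2322
RTINSECONDS=619.8
146 100
159 100
172 100
186 100
200 100
214 100
300 100
END IONS
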