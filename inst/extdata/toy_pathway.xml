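<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:syn00001" org="syn" number="00001" title="toy compartment chain">
  <entry id="1" name="cpd:C00022" type="compound">
    <graphics name="C00022" type="circle" x="100" y="200" width="8" height="8"/>
  </entry>
  <entry id="2" name="cpd:C00024" type="compound">
    <graphics name="C00024" type="circle" x="200" y="200" width="8" height="8"/>
  </entry>
  <entry id="3" name="cpd:C00186" type="compound">
    <graphics name="C00186" type="circle" x="300" y="200" width="8" height="8"/>
  </entry>
  <entry id="4" name="hsa:9001" type="gene" reaction="rn:R90001">
    <graphics name="TOYM1" type="rectangle" x="150" y="160" width="46" height="17"/>
  </entry>
  <entry id="5" name="hsa:9002" type="gene" reaction="rn:R90002">
    <graphics name="TOYC1" type="rectangle" x="250" y="160" width="46" height="17"/>
  </entry>
  <reaction id="4" name="rn:R90001" type="irreversible">
    <substrate id="1" name="cpd:C00022"/>
    <product id="2" name="cpd:C00024"/>
  </reaction>
  <reaction id="5" name="rn:R90002" type="irreversible">
    <substrate id="2" name="cpd:C00024"/>
    <product id="3" name="cpd:C00186"/>
  </reaction>
</pathway>
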