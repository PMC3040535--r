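<?xml version="1.0" encoding="UTF-8"?>
<!-- Hand-written synthetic UniProt-style fixture (3 entries) used by the
     I/O tests; not derived from any real UniProt record. -->
<uniprot xmlns="http://uniprot.org/uniprot">
  <entry dataset="Swiss-Prot">
    <accession>P00001</accession>
    <name>TEST1_SYNTH</name>
    <feature type="modified residue" description="Phosphoserine">
      <location><position position="5"/></location>
    </feature>
    <feature type="modified residue"
             description="Phosphothreonine; by similarity">
      <location><position position="8"/></location>
    </feature>
    <feature type="modified residue" description="N6-acetyllysine">
      <location><position position="3"/></location>
    </feature>
    <sequence length="10">MAKWSVATRL</sequence>
  </entry>
  <entry dataset="Swiss-Prot">
    <accession>P00002</accession>
    <name>TEST2_SYNTH</name>
    <feature type="modified residue" description="Phosphotyrosine">
      <location><position position="4"/></location>
    </feature>
    <feature type="modified residue"
             description="Phosphoserine; by similarity">
      <location><position position="2"/></location>
    </feature>
    <sequence length="7">MSAYVLK</sequence>
  </entry>
  <entry dataset="Swiss-Prot">
    <accession>P00003</accession>
    <name>TEST3_SYNTH</name>
    <feature type="modified residue" description="Phosphoserine">
      <location><position position="3"/></location>
    </feature>
    <sequence length="6">MAAAKL</sequence>
  </entry>
</uniprot>
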