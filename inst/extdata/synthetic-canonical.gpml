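<?xml version="1.0" encoding="UTF-8"?>
<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Synthetic pathway (seed 7)" Organism="Homo sapiens" Version="2013a">
  <Graphics BoardWidth="800" BoardHeight="700"/>
  <DataNode TextLabel="GENE1001" GraphId="dn1" Type="GeneProduct">
    <Graphics CenterX="100" CenterY="80" Width="80" Height="20" ShapeType="Rectangle" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
    <Xref Database="Entrez Gene" ID="1001"/>
  </DataNode>
  <DataNode TextLabel="GENE1001" GraphId="dn2" Type="GeneProduct">
    <Graphics CenterX="250" CenterY="80" Width="80" Height="20" ShapeType="Rectangle" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
    <Xref Database="Entrez Gene" ID="1001"/>
  </DataNode>
  <DataNode TextLabel="GENE2003" GraphId="dn3" Type="GeneProduct">
    <Graphics CenterX="400" CenterY="80" Width="80" Height="20" ShapeType="Rectangle" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
    <Xref Database="Entrez Gene" ID="2003"/>
  </DataNode>
  <DataNode TextLabel="GENE2004" GraphId="dn4" Type="GeneProduct" GroupRef="grp1">
    <Graphics CenterX="550" CenterY="80" Width="80" Height="20" ShapeType="Rectangle" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
    <Xref Database="Entrez Gene" ID="2004"/>
  </DataNode>
  <DataNode TextLabel="GENE2005" GraphId="dn5" Type="GeneProduct" GroupRef="grp1">
    <Graphics CenterX="100" CenterY="180" Width="80" Height="20" ShapeType="Rectangle" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
    <Xref Database="Entrez Gene" ID="2005"/>
  </DataNode>
  <Interaction GraphId="int1">
    <Graphics FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1">
      <Point X="250" Y="80" GraphRef="dn2"/>
      <Point X="400" Y="80" GraphRef="dn3" ArrowHead="Arrow"/>
      <Anchor Position="0.5" Shape="None" GraphId="anc1"/>
    </Graphics>
    <Xref Database="" ID=""/>
  </Interaction>
  <Interaction GraphId="int2">
    <Graphics FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1">
      <Point X="400" Y="80" GraphRef="dn3"/>
      <Point X="550" Y="80" GraphRef="dn4" ArrowHead="TBar"/>
    </Graphics>
    <Xref Database="" ID=""/>
  </Interaction>
  <Interaction GraphId="int3">
    <Graphics FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1">
      <Point X="550" Y="80" GraphRef="dn4"/>
      <Point X="100" Y="180" GraphRef="dn5" ArrowHead="mim-inhibition"/>
    </Graphics>
    <Xref Database="" ID=""/>
  </Interaction>
  <Label TextLabel="Annotation 1" GraphId="lbl1">
    <Graphics CenterX="250" CenterY="480" Width="120" Height="16" ShapeType="None" FillColor="FFFFFF" Color="000000" ZOrder="0" LineThickness="1"/>
  </Label>
  <Shape GraphId="shp1">
    <Graphics CenterX="400" CenterY="540" Width="200" Height="120" ShapeType="Oval" FillColor="FFFFFF" Color="808080" ZOrder="0" LineThickness="1"/>
  </Shape>
  <Group GroupId="grp1" GraphId="grpnode1" Style="Complex"/>
</Pathway>

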