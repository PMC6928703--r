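<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>900001</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate>
              <Year>2019</Year>
            </PubDate>
          </JournalIssue>
          <Title>Journal of Hypertension</Title>
        </Journal>
        <ArticleTitle>Beta-blocker versus ACE inhibitor therapy in female patients with elevated blood pressure</ArticleTitle>
        <Abstract>
          <AbstractText>Elevated blood pressure in female patients often requires a change of therapy. We randomized participants to a beta-blocker or an ACE inhibitor arm. Blood pressure control was the primary outcome. The ACE inhibitor group achieved lower blood pressure.</AbstractText>
        </Abstract>
        <PublicationTypeList>
          <PublicationType>Randomized Controlled Trial</PublicationType>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName>Hypertension</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Adrenergic beta-Antagonists</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Angiotensin-Converting Enzyme Inhibitors</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Female</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>900002</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate>
              <Year>2021</Year>
            </PubDate>
          </JournalIssue>
          <Title>Cochrane Database</Title>
        </Journal>
        <ArticleTitle>Systematic review of antihypertensive drug classes in women</ArticleTitle>
        <Abstract>
          <AbstractText>We reviewed trials comparing antihypertensive drug classes. Beta-blocker and ACE inhibitor regimens were compared for blood pressure reduction in female participants.</AbstractText>
        </Abstract>
        <PublicationTypeList>
          <PublicationType>Systematic Review</PublicationType>
        </PublicationTypeList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName>Hypertension</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Female</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Antihypertensive Agents</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>900003</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate>
              <Year>2020</Year>
            </PubDate>
          </JournalIssue>
          <Title>BMJ Open</Title>
        </Journal>
        <ArticleTitle>ACE inhibitor adherence and blood pressure outcomes in a female cohort</ArticleTitle>
        <Abstract>
          <AbstractText>A cohort of female patients using an ACE inhibitor was followed for two years. Blood pressure outcomes improved with adherence.</AbstractText>
        </Abstract>
        <PublicationTypeList>
          <PublicationType>Cohort Study</PublicationType>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName>Medication Adherence</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Female</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Blood Pressure</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
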